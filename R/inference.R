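#' Permutation-test results
#'
#' Container for resampling inferences: the observed statistic, the null
#' distribution, the add-one two-sided p-value
#' `(1 + #\{|null| >= |observed|\}) / (1 + n_permutations)`, the permutation
#' count and seed.  Ties with the observed magnitude count toward the null
#' exceedances (conservative).
#'
#' @param observed Observed statistic.
#' @param null_stats Numeric vector of permuted statistics.
#' @param seed Seed used for the permutations.
#' @param statistic Human-readable description of the statistic.
#' @param n Problem size (e.g. number of plants or nodules).
#' @param extra Named list of additional fields stored on the object.
#' @return A list of class `perm_test`.
#' @export
perm_test <- function(observed, null_stats, seed, statistic = "statistic",
                      n = NA_integer_, extra = list()) {
  n_perm <- length(null_stats)
  p <- (1 + sum(abs(null_stats) >= abs(observed) - 1e-12)) / (1 + n_perm)
  structure(c(list(observed_stat = observed, null_stats = null_stats,
                   p_value = p, n_permutations = n_perm, seed = seed,
                   statistic = statistic, n = n), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$statistic, "\n", sep = "")
  cat("  observed: ", format(x$observed_stat, digits = 4),
      "   p = ", format(x$p_value, digits = 4),
      " (", x$n_permutations, " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, estimate = x$observed_stat,
                 p.value = x$p_value)
}

#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(estimate = x$observed_stat, p.value = x$p_value,
                 n_permutations = x$n_permutations, n = x$n, seed = x$seed)
}

#' Cluster-aware permutation contrast between nodule occupants
#'
#' Tests whether a per-nodule measure (e.g. total or partial nodule area)
#' differs between Fix+ and Fix- occupants while respecting the clustering of
#' nodules within plants.  The statistic is the difference in occupant-class
#' means of *plant-level* means, so each plant contributes once per class; the
#' null distribution re-shuffles occupant labels among nodules independently
#' within each plant, which preserves per-plant class counts and any
#' between-plant heterogeneity.
#'
#' @param data A data frame of nodules.
#' @param value,occupant,plant Columns (unquoted) holding the measure, the
#'   occupant label (exactly two classes) and the plant id.
#' @param n_perm Number of label permutations (ignored when `exact = TRUE`).
#' @param seed Integer seed for the permutations.
#' @param exact If `TRUE`, enumerate every distinct within-plant relabeling
#'   (only feasible for small instances) and report the exact p-value
#'   `#\{|null| >= |observed|\} / N` over the full enumeration (which includes
#'   the observed labeling).
#' @return A [perm_test()]; `observed_stat` is mean(class 1) - mean(class 2)
#'   with classes in sorted label order, stored in `$classes`.
#' @export
cluster_permutation_contrast <- function(data, value, occupant, plant,
                                         n_perm = 9999, seed = 1L,
                                         exact = FALSE) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(occupant), data))
  pl <- as.character(rlang::eval_tidy(rlang::enquo(plant), data))
  stopifnot(length(v) == length(g), length(v) == length(pl))
  classes <- sort(unique(g))
  if (length(classes) != 2L) {
    stop("need exactly two occupant classes, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (length(unique(pl)) < 2L) {
    stop("need nodules from at least two plants", call. = FALSE)
  }
  split_idx <- split(seq_along(v), pl)
  vals <- lapply(split_idx, function(i) v[i])
  nA <- vapply(split_idx, function(i) sum(g[i] == classes[1]), integer(1))
  ntot <- lengths(split_idx)
  tots <- vapply(vals, sum, numeric(1))
  if (all(nA == 0L) || all(nA == ntot)) {
    stop("contrast undefined: a class is absent from every plant", call. = FALSE)
  }
  stat_from_sums <- function(sA) {
    mA <- sA[nA > 0L] / nA[nA > 0L]
    mB <- (tots[nA < ntot] - sA[nA < ntot]) / (ntot[nA < ntot] - nA[nA < ntot])
    mean(mA) - mean(mB)
  }
  obs_sA <- vapply(seq_along(vals), function(i) sum(vals[[i]][g[split_idx[[i]]] == classes[1]]),
                   numeric(1))
  observed <- stat_from_sums(obs_sA)
  set.seed(seed)
  if (exact) {
    combos <- lapply(seq_along(vals), function(i) {
      if (nA[i] == 0L || nA[i] == ntot[i]) return(matrix(sum(vals[[i]]) * (nA[i] > 0), 1L))
      cbn <- utils::combn(ntot[i], nA[i])
      matrix(apply(cbn, 2, function(j) sum(vals[[i]][j])), ncol = 1L)
    })
    # cross all per-plant subset sums: one column per plant, one row per
    # distinct joint relabeling
    grid <- Reduce(function(acc, s) {
      expand <- expand.grid(a = seq_len(nrow(acc)), b = seq_len(nrow(s)))
      cbind(acc[expand$a, , drop = FALSE], s[expand$b, , drop = FALSE])
    }, combos)
    null <- apply(grid, 1, stat_from_sums)
    p <- sum(abs(null) >= abs(observed) - 1e-12) / length(null)
    res <- perm_test(observed, null, seed, statistic = "occupant contrast (exact)",
                     n = length(v), extra = list(classes = classes, exact = TRUE))
    res$p_value <- p
    return(res)
  }
  null <- numeric(n_perm)
  k <- length(vals)
  for (b in seq_len(n_perm)) {
    sA <- numeric(k)
    for (i in seq_len(k)) {
      ni <- ntot[i]; na <- nA[i]
      sA[i] <- if (na == 0L) 0 else if (na == ni) tots[i] else
        sum(vals[[i]][sample.int(ni, na)])
    }
    null[b] <- stat_from_sums(sA)
  }
  perm_test(observed, null, seed, statistic = "occupant contrast",
            n = length(v), extra = list(classes = classes, exact = FALSE))
}

#' Association between sanctions strictness and virus titer
#'
#' Estimates the slope of virus titer on within-nodule (or among-nodule)
#' sanctions strictness across plants, after centering titer within
#' marker-covariate groups (the Fix+ marker color, which controls for
#' fluorophore-detection differences in the reciprocally labeled
#' co-inoculation treatments).  Significance comes from permuting strictness
#' values across plants *within* covariate groups.  Both variables are
#' measured responses, so the direction of causality is not identified; the
#' slope describes an association only.
#'
#' @param data A data frame of plants.
#' @param strictness,titer Columns (unquoted) with per-plant strictness and
#'   titer; rows with `NA` in either are dropped.
#' @param marker Optional column (unquoted) with the covariate labels; omit to
#'   center globally.
#' @param n_perm,seed Permutation settings.
#' @return A [perm_test()] whose `observed_stat` is the slope (titer units per
#'   unit strictness); also stored as `$slope`.
#' @export
strictness_titer_association <- function(data, strictness, titer, marker = NULL,
                                         n_perm = 9999, seed = 1L) {
  s <- rlang::eval_tidy(rlang::enquo(strictness), data)
  t <- rlang::eval_tidy(rlang::enquo(titer), data)
  mq <- rlang::enquo(marker)
  m <- if (rlang::quo_is_null(mq)) rep("all", length(s)) else
    as.character(rlang::eval_tidy(mq, data))
  keep <- !is.na(s) & !is.na(t)
  s <- s[keep]; t <- t[keep]; m <- m[keep]
  if (length(s) < 4L) {
    stop("need at least 4 plants with defined strictness and titer", call. = FALSE)
  }
  if (stats::sd(s) == 0 || sum((s - stats::ave(s, m))^2) == 0) {
    stop("association undefined: strictness is constant", call. = FALSE)
  }
  # center both variables within covariate groups (pooled within-group slope)
  tc <- t - stats::ave(t, m)
  sc <- s - stats::ave(s, m)
  slope_of <- function(sv) sum(sv * tc) / sum(sv^2)
  observed <- slope_of(sc)
  set.seed(seed)
  groups <- split(seq_along(s), m)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    sp <- sc
    for (i in groups) sp[i] <- sc[i][sample.int(length(i))]
    null[b] <- slope_of(sp)
  }
  perm_test(observed, null, seed,
            statistic = "titer ~ strictness slope (marker-stratified)",
            n = length(s),
            extra = list(slope = observed,
                         direction = if (observed > 0) "positive" else "non-positive"))
}

#' Pearson correlation with a t-based p-value
#'
#' Product-moment correlation; the p-value uses the t transform with n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A tibble: `estimate` (r), `p.value`, `n`.
#' @examples
#' pearson_cor(c(1, 2, 3), c(1, 2, 4))  # r ~ 0.982
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                 n = length(x))
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down Holm correction: p-values are sorted ascending, the i-th smallest
#' is multiplied by (m - i + 1), a running maximum enforces monotonicity, the
#' result is capped at 1 and returned in the input order.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.03, 0.01, 0.04))  # 0.06 0.03 0.06
#' @export
holm_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}
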