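#' Validate detection against ground truth (or manual counts)
#'
#' Compares per-plant detected nodule counts with reference counts, and
#' matches individual detected nodules to reference nodules by nearest
#' centroid to compare sizes.  This mirrors the validation performed on real
#' mosaics, where automated counts were checked against manual counts and
#' automated sizes against hand-traced outlines (automated sizes tend to run
#' slightly small because thresholding trims dim nodule rims).
#'
#' @param detected Per-nodule tibble from [detect_pipeline()] runs
#'   (`plant_id`, `cx`, `cy`, `area`).
#' @param truth Reference tibble (`plant_id`, `cx`, `cy`, `radius_px`,
#'   `true_total_area`), e.g. from [sample_nodule_population()].
#' @param match_slack Extra matching radius in pixels beyond each reference
#'   nodule's own radius.
#' @return A list of class `validation_report`: `count_r`/`count_p` (Pearson
#'   correlation of per-plant counts), `area_r`/`area_p` (over matched
#'   nodules), `n_matched`, `mean_size_bias` (mean detected - true area, mm^2),
#'   `per_plant` and `matches` tibbles, and `notes` flagging degenerate cases
#'   (e.g. constant counts, for which the correlation is undefined rather than
#'   silently `NaN`).
#' @export
validate_detection <- function(detected, truth, match_slack = 10) {
  stopifnot(is.data.frame(detected), is.data.frame(truth))
  plants_d <- unique(detected$plant_id)
  plants_t <- unique(truth$plant_id)
  if (!setequal(plants_d, plants_t)) {
    stop("detected and truth cover different plants: ",
         paste(union(setdiff(plants_d, plants_t), setdiff(plants_t, plants_d)),
               collapse = ", "), call. = FALSE)
  }
  plants <- sort(plants_t)
  if (length(plants) < 3L) {
    stop("need at least 3 paired plants to validate", call. = FALSE)
  }
  per_plant <- tibble::tibble(
    plant_id = plants,
    n_true = vapply(plants, function(p) sum(truth$plant_id == p), numeric(1)),
    n_detected = vapply(plants, function(p) sum(detected$plant_id == p), numeric(1))
  )
  notes <- character(0)
  if (stats::sd(per_plant$n_true) == 0 || stats::sd(per_plant$n_detected) == 0) {
    notes <- c(notes, "count correlation undefined: constant counts")
    count_r <- NA_real_; count_p <- NA_real_
  } else {
    ct <- stats::cor.test(per_plant$n_true, per_plant$n_detected)
    count_r <- unname(ct$estimate); count_p <- ct$p.value
  }
  matches <- dplyr::bind_rows(lapply(plants, function(p) {
    match_nodules(truth[truth$plant_id == p, , drop = FALSE],
                  detected[detected$plant_id == p, , drop = FALSE], match_slack)
  }))
  if (nrow(matches) >= 3L && stats::sd(matches$true_area) > 0 &&
      stats::sd(matches$detected_area) > 0) {
    at <- stats::cor.test(matches$true_area, matches$detected_area)
    area_r <- unname(at$estimate); area_p <- at$p.value
  } else {
    notes <- c(notes, "area correlation undefined: too few or constant matches")
    area_r <- NA_real_; area_p <- NA_real_
  }
  structure(list(
    count_r = count_r, count_p = count_p,
    area_r = area_r, area_p = area_p,
    n_matched = nrow(matches),
    mean_size_bias = if (nrow(matches)) mean(matches$detected_area - matches$true_area) else NA_real_,
    per_plant = per_plant, matches = matches, notes = notes
  ), class = "validation_report")
}

# Greedy one-to-one nearest-centroid matching within one plant.
match_nodules <- function(truth, detected, match_slack) {
  if (nrow(truth) == 0L || nrow(detected) == 0L) {
    return(tibble::tibble(plant_id = character(), true_id = character(),
                          detected_id = character(), dist_px = numeric(),
                          true_area = numeric(), detected_area = numeric()))
  }
  d2 <- outer(truth$cx, detected$cx, "-")^2 + outer(truth$cy, detected$cy, "-")^2
  limit <- truth$radius_px + match_slack
  rows <- integer(0); cols <- integer(0); dist <- numeric(0)
  repeat {
    m <- which.min(d2)
    if (!length(m) || !is.finite(d2[m])) break
    i <- ((m - 1L) %% nrow(d2)) + 1L
    j <- ((m - 1L) %/% nrow(d2)) + 1L
    if (sqrt(d2[m]) > limit[i]) break
    rows <- c(rows, i); cols <- c(cols, j); dist <- c(dist, sqrt(d2[m]))
    d2[i, ] <- Inf; d2[, j] <- Inf
  }
  tibble::tibble(
    plant_id = truth$plant_id[rows],
    true_id = truth$nodule_id[rows],
    detected_id = detected$nodule_id[cols],
    dist_px = dist,
    true_area = truth$true_total_area[rows],
    detected_area = detected$area[cols]
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  per-plant count r: ", format(x$count_r, digits = 3),
      "  (", nrow(x$per_plant), " plants)\n", sep = "")
  cat("  matched-area r:    ", format(x$area_r, digits = 3),
      "  (", x$n_matched, " nodules)\n", sep = "")
  cat("  mean size bias (detected - true): ",
      format(x$mean_size_bias, digits = 3), " mm^2\n", sep = "")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(count_r = x$count_r, count_p = x$count_p,
                 area_r = x$area_r, area_p = x$area_p,
                 n_plants = nrow(x$per_plant), n_matched = x$n_matched,
                 mean_size_bias = x$mean_size_bias)
}

#' Simulate a detection-validation benchmark
#'
#' Generates `n_mosaics` co-inoculated plants whose nodule counts are drawn
#' uniformly over `count_range`, renders their mosaics under the configured
#' noise and touching-nodule rate, runs the detection pipeline, and returns
#' everything needed to score count and size recovery.
#'
#' @param n_mosaics Number of synthetic root mosaics.
#' @param cfg An [effect_config()].
#' @param det_cfg A [detection_config()].
#' @param count_range Integer range of true nodule counts per mosaic.
#' @param seed Integer seed.
#' @return A list: `truth` (ground-truth nodule tibble), `detected`
#'   (per-nodule detection tibble), `ledgers`, and the `report` from
#'   [validate_detection()].
#' @export
simulate_benchmark <- function(n_mosaics = 60, cfg = effect_config(),
                               det_cfg = detection_config(pixel_scale = cfg$pixel_scale),
                               count_range = c(20, 150), seed = 1L) {
  set.seed(seed)
  inocs <- rep(c("fix_plus", "fix_minus", "co_A", "co_B"), length.out = n_mosaics)
  design <- build_design(1L, c("wild", "domesticated"),
                         unique(inocs), c("none"))
  design <- dplyr::bind_rows(lapply(seq_len(n_mosaics), function(i) {
    row <- design[design$inoculum == inocs[i], ][((i - 1L) %/% 4L) %% 2L + 1L, ]
    row$plant_id <- sprintf("M%03d_%s", i, row$inoculum)
    row
  }))
  counts <- sample(count_range[1]:count_range[2], n_mosaics, replace = TRUE)
  truth <- sample_nodule_population(design, cfg, counts = counts)
  det <- vector("list", n_mosaics)
  led <- vector("list", n_mosaics)
  for (i in seq_len(n_mosaics)) {
    nd <- truth[truth$plant_id == design$plant_id[i], , drop = FALSE]
    stack <- render_mosaic(nd, cfg)
    res <- detect_pipeline(stack, design[i, ], det_cfg)
    det[[i]] <- res$nodules
    led[[i]] <- res$ledger
  }
  detected <- dplyr::bind_rows(det)
  # non-fluorescent nodules are invisible to the fluorescence pipeline by
  # design; score recovery against the fluorescent truth
  fluor_truth <- truth[truth$occupancy_kind != "nonfluorescent", , drop = FALSE]
  report <- validate_detection(detected, fluor_truth)
  list(truth = truth, detected = detected,
       ledgers = dplyr::bind_rows(led), report = report, design = design)
}
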