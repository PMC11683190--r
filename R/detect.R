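#' Detection configuration
#'
#' Settings for the nodule-detection pipeline: per-channel intensity
#' thresholds (absolute, or `"auto"` for Otsu's criterion computed per channel
#' after normalizing by that channel's mean brightness — which makes the
#' threshold robust to the red/green brightness imbalance), minimum and
#' maximum nodule sizes, the minor-channel fraction above which a nodule is
#' called mixed-color, and the pixel scale.
#'
#' @param red_threshold,green_threshold Absolute intensity cutoffs (in image
#'   digital numbers) or the string `"auto"`.
#' @param min_area,max_area Retained nodule size range, mm^2.
#' @param mixed_minor_fraction Fraction of nodule area (in (0, 0.5]) the minor
#'   channel must exceed for a mixed-color call.
#' @param pixel_scale Millimetres per pixel used to convert pixel counts to mm^2.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(red_threshold = 60, green_threshold = 30,
                             min_area = 0.05, max_area = 12,
                             mixed_minor_fraction = 0.10, pixel_scale = 0.01) {
  ok_thr <- function(t) identical(t, "auto") || (is.numeric(t) && length(t) == 1L)
  if (!ok_thr(red_threshold) || !ok_thr(green_threshold)) {
    stop("thresholds must be numeric scalars or \"auto\"", call. = FALSE)
  }
  if (!(min_area < max_area)) {
    stop("min_area must be smaller than max_area", call. = FALSE)
  }
  if (!(mixed_minor_fraction > 0 && mixed_minor_fraction <= 0.5)) {
    stop("mixed_minor_fraction must lie in (0, 0.5]", call. = FALSE)
  }
  structure(list(red_threshold = red_threshold, green_threshold = green_threshold,
                 min_area = min_area, max_area = max_area,
                 mixed_minor_fraction = mixed_minor_fraction,
                 pixel_scale = pixel_scale),
            class = "detection_config")
}

# Resolve one channel's threshold; "auto" = Otsu on the mean-normalized channel.
resolve_threshold <- function(channel, thr, bit_depth) {
  if (identical(thr, "auto")) {
    mu <- mean(channel)
    if (mu <= 0) return(Inf)  # empty channel: nothing can pass
    xn <- channel / mu
    t <- EBImage::otsu(EBImage::Image(xn / max(xn)), range = c(0, 1)) * max(xn)
    thr <- t * mu
  }
  thr
}

#' Segment candidate nodule features from the fluorescence layers
#'
#' Foreground is the union of red-above-threshold and green-above-threshold
#' pixels; features are its 8-connected components.  No size filtering is
#' applied at this stage.
#'
#' @param stack A [channel_stack()].
#' @param cfg A [detection_config()].
#' @return A list with `labels` (integer matrix, 0 = background), `features`
#'   (tibble: `feature_id`, `n_pixels`, bounding box), and the resolved
#'   `red_threshold`/`green_threshold`.
#' @export
segment_features <- function(stack, cfg) {
  stopifnot(inherits(stack, "channel_stack"), inherits(cfg, "detection_config"))
  thr_r <- resolve_threshold(stack$red, cfg$red_threshold, stack$bit_depth)
  thr_g <- resolve_threshold(stack$green, cfg$green_threshold, stack$bit_depth)
  if (is.finite(thr_r) && thr_r <= 0 || is.finite(thr_g) && thr_g <= 0) {
    stop("degenerate threshold (<= 0): the whole image would be foreground",
         call. = FALSE)
  }
  fg <- (stack$red >= thr_r) | (stack$green >= thr_g)
  labels <- label_components_8(fg)
  k <- max(labels)
  if (k == 0L) {
    features <- tibble::tibble(feature_id = integer(), n_pixels = integer(),
                               xmin = integer(), xmax = integer(),
                               ymin = integer(), ymax = integer())
  } else {
    idx <- which(labels > 0L)
    labv <- labels[idx]
    nr <- nrow(labels)
    y <- ((idx - 1L) %% nr) + 1L
    x <- ((idx - 1L) %/% nr) + 1L
    features <- tibble::tibble(
      feature_id = seq_len(k),
      n_pixels = tabulate(labv, k),
      xmin = as.integer(tapply(x, labv, min)),
      xmax = as.integer(tapply(x, labv, max)),
      ymin = as.integer(tapply(y, labv, min)),
      ymax = as.integer(tapply(y, labv, max))
    )
  }
  list(labels = labels, features = features,
       red_threshold = thr_r, green_threshold = thr_g)
}

# 8-connected labeling: EBImage's 4-connected bwlabel followed by a
# union-find merge of diagonally adjacent labels.
label_components_8 <- function(fg) {
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  k <- max(lab)
  if (k == 0L) return(lab)
  n <- nrow(lab); m <- ncol(lab)
  a <- as.vector(lab[-n, -m]); b <- as.vector(lab[-1, -1])
  c_ <- as.vector(lab[-1, -m]); d <- as.vector(lab[-n, -1])
  pairs <- rbind(cbind(a, b), cbind(c_, d))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Fill holes inside segmented features
#'
#' Background regions (4-connected) fully enclosed by a feature are merged
#' into the enclosing feature; the outer background is untouched.  Returns the
#' filled label map and the number of hole regions removed, which the filter
#' ledger counts among the initially detected features (as particle-analysis
#' macros do).
#'
#' @param labels Integer label matrix from [segment_features()].
#' @return A list with `labels` (filled) and `n_holes_removed`.
#' @export
remove_holes <- function(labels) {
  bg <- labels == 0L
  if (!any(bg) || !any(labels > 0L)) return(list(labels = labels, n_holes_removed = 0L))
  bglab <- EBImage::bwlabel(bg)
  bglab <- matrix(as.integer(bglab), nrow(labels), ncol(labels))
  n <- nrow(labels); m <- ncol(labels)
  border <- unique(c(bglab[1, ], bglab[n, ], bglab[, 1], bglab[, m]))
  holes <- setdiff(unique(bglab[bglab > 0L]), border)
  for (h in holes) {
    idx <- which(bglab == h)
    nb <- c(labels[idx - 1L], labels[idx + 1L], labels[idx - n], labels[idx + n])
    labels[idx] <- max(nb)
  }
  list(labels = labels, n_holes_removed = length(holes))
}

#' Filter features by physical size and account for every removal
#'
#' Drops features smaller than `min_area` or larger than `max_area` (mm^2,
#' via `pixel_scale^2`) and returns a ledger satisfying the exact balance
#' `n_initial_features = n_holes_removed + n_below_min + n_above_max +
#' n_retained`.
#'
#' @param features Feature tibble with `feature_id` and `n_pixels`.
#' @param cfg A [detection_config()].
#' @param n_holes_removed Hole count from [remove_holes()], folded into the
#'   initial feature count.
#' @return A list with `features` (retained rows, with `area` in mm^2) and
#'   `ledger` (one-row tibble).
#' @export
filter_by_size <- function(features, cfg, n_holes_removed = 0L) {
  stopifnot(inherits(cfg, "detection_config"))
  features$area <- features$n_pixels * cfg$pixel_scale^2
  below <- features$area < cfg$min_area
  above <- features$area > cfg$max_area
  retained <- features[!below & !above, , drop = FALSE]
  ledger <- tibble::tibble(
    n_initial_features = nrow(features) + n_holes_removed,
    n_holes_removed = as.integer(n_holes_removed),
    n_below_min = sum(below),
    n_above_max = sum(above),
    n_retained = nrow(retained)
  )
  list(features = retained, ledger = ledger)
}

#' Per-channel occupancy of each feature
#'
#' For every retained feature, the percentage of its pixels at or above the
#' red (resp. green) threshold.  Channels are assessed independently, so a
#' pixel bright in both channels counts toward both percentages.
#'
#' @param labels Filled label matrix.
#' @param stack The [channel_stack()] the labels were derived from.
#' @param red_threshold,green_threshold Resolved numeric thresholds.
#' @param feature_ids Features to quantify (default: all labels present).
#' @return A tibble: `feature_id`, `n_pixels`, `pct_red`, `pct_green`,
#'   centroid `cx`, `cy` (pixel coordinates, origin top-left).
#' @export
quantify_occupancy <- function(labels, stack, red_threshold, green_threshold,
                               feature_ids = NULL) {
  k <- max(labels)
  if (k == 0L) {
    return(tibble::tibble(feature_id = integer(), n_pixels = integer(),
                          pct_red = numeric(), pct_green = numeric(),
                          cx = numeric(), cy = numeric()))
  }
  idx <- which(labels > 0L)
  labv <- labels[idx]
  counts <- tabulate(labv, k)
  if (any(counts[unique(labv)] == 0L)) stop("internal: empty feature", call. = FALSE)
  red_hit <- tabulate(labv[stack$red[idx] >= red_threshold], k)
  green_hit <- tabulate(labv[stack$green[idx] >= green_threshold], k)
  nr <- nrow(labels)
  y <- ((idx - 1L) %% nr) + 1L
  x <- ((idx - 1L) %/% nr) + 1L
  out <- tibble::tibble(
    feature_id = seq_len(k),
    n_pixels = counts,
    pct_red = 100 * red_hit / pmax(counts, 1L),
    pct_green = 100 * green_hit / pmax(counts, 1L),
    cx = as.numeric(rowsum(x, labv)[, 1] / counts[sort(unique(labv))]),
    cy = as.numeric(rowsum(y, labv)[, 1] / counts[sort(unique(labv))])
  )
  if (!is.null(feature_ids)) out <- out[out$feature_id %in% feature_ids, , drop = FALSE]
  out
}

#' Classify a nodule from its channel occupancies
#'
#' A nodule showing at least `mixed_minor_fraction` of its area in *both*
#' channels is `mixed_color`; exactly one channel above that fraction gives a
#' single-color call; neither gives `nonfluorescent`.
#'
#' @param pct_red,pct_green Percentages in \[0, 100\] (vectorized).
#' @param cfg A [detection_config()].
#' @return Character vector: `"single_red"`, `"single_green"`,
#'   `"mixed_color"` or `"nonfluorescent"`.
#' @examples
#' classify_nodule(c(95, 60, 0), c(5, 40, 0), detection_config())
#' @export
classify_nodule <- function(pct_red, pct_green, cfg) {
  stopifnot(inherits(cfg, "detection_config"))
  if (any(pct_red < 0 | pct_red > 100 | pct_green < 0 | pct_green > 100)) {
    stop("occupancy percentages must lie in [0, 100]", call. = FALSE)
  }
  cut <- 100 * cfg$mixed_minor_fraction
  dplyr::case_when(
    pct_red >= cut & pct_green >= cut ~ "mixed_color",
    pct_red >= cut ~ "single_red",
    pct_green >= cut ~ "single_green",
    TRUE ~ "nonfluorescent"
  )
}

#' Map fluorophore colors to strains under the plant's labeling scheme
#'
#' Co-inoculation version A labels Fix+ red and Fix- green; version B is the
#' reciprocal; in 1-strain inocula both colors carry the same strain.  For
#' mixed-color nodules on co-inoculated plants the partial area of each strain
#' is the nodule area split in proportion to the two channel occupancies.
#' Mixed-color nodules on 1-strain plants (e.g. touching nodules of the two
#' fluorophores) resolve to that single strain.  Non-fluorescent nodules get
#' occupant `unknown` and are excluded from sanctions.  Fluorescent features
#' on uninoculated plants raise a contamination warning.
#'
#' @param nodule_class Character vector of classes from [classify_nodule()].
#' @param inoculum The plant's inoculum level.
#' @param pct_red,pct_green Channel occupancies.
#' @param area Nodule areas, mm^2.
#' @return A tibble: `occupant` (`fix_plus`, `fix_minus`, `mixed`, `unknown`),
#'   `partial_area_fix_plus`, `partial_area_fix_minus`.
#' @export
assign_strains <- function(nodule_class, inoculum, pct_red, pct_green, area) {
  if (identical(inoculum, "none")) {
    if (any(nodule_class != "nonfluorescent")) {
      warning("fluorescent nodules on an uninoculated plant: possible ",
              "cross-contamination; occupant set to unknown", call. = FALSE)
    }
    return(tibble::tibble(occupant = rep("unknown", length(nodule_class)),
                          partial_area_fix_plus = 0, partial_area_fix_minus = 0))
  }
  cols <- inoculum_colors(inoculum)
  strain_of <- c(red = cols$red, green = cols$green)
  occupant <- character(length(nodule_class))
  pfp <- pfm <- numeric(length(nodule_class))
  for (i in seq_along(nodule_class)) {
    cl <- nodule_class[i]
    if (cl == "nonfluorescent") {
      occupant[i] <- "unknown"
    } else if (cl == "single_red") {
      occupant[i] <- strain_of[["red"]]
    } else if (cl == "single_green") {
      occupant[i] <- strain_of[["green"]]
    } else {  # mixed_color
      if (cols$both_strains) {
        occupant[i] <- "mixed"
        tot <- pct_red[i] + pct_green[i]
        red_area <- area[i] * pct_red[i] / tot
        green_area <- area[i] * pct_green[i] / tot
        if (strain_of[["red"]] == "fix_plus") {
          pfp[i] <- red_area; pfm[i] <- green_area
        } else {
          pfp[i] <- green_area; pfm[i] <- red_area
        }
        next
      }
      occupant[i] <- strain_of[["red"]]  # 1-strain: both colors same strain
    }
    if (occupant[i] == "fix_plus") pfp[i] <- area[i]
    if (occupant[i] == "fix_minus") pfm[i] <- area[i]
  }
  tibble::tibble(occupant = occupant,
                 partial_area_fix_plus = pfp,
                 partial_area_fix_minus = pfm)
}

#' End-to-end nodule detection for one plant
#'
#' Composes segmentation, hole removal, size filtering, occupancy
#' quantification, classification and strain assignment, and returns
#' CSV-ready per-nodule records together with the filter ledger.
#'
#' @param stack A [channel_stack()].
#' @param plant One design row (tibble) giving `plant_id` and `inoculum`.
#' @param cfg A [detection_config()].
#' @return A list of class `detection`: `nodules` (tibble with `nodule_id`,
#'   `plant_id`, centroid, `area`, `pct_red`, `pct_green`, `nodule_class`,
#'   `occupant`, partial areas) and `ledger` (one-row tibble).
#' @export
detect_pipeline <- function(stack, plant, cfg = detection_config()) {
  stopifnot(is.data.frame(plant), nrow(plant) == 1L)
  pid <- plant$plant_id
  res <- tryCatch({
    seg <- segment_features(stack, cfg)
    fill <- remove_holes(seg$labels)
    occ_all <- quantify_occupancy(fill$labels, stack,
                                  seg$red_threshold, seg$green_threshold)
    flt <- filter_by_size(occ_all, cfg, n_holes_removed = fill$n_holes_removed)
    feats <- flt$features
    if (nrow(feats)) {
      feats$nodule_class <- classify_nodule(feats$pct_red, feats$pct_green, cfg)
      assigned <- assign_strains(feats$nodule_class, plant$inoculum,
                                 feats$pct_red, feats$pct_green, feats$area)
      feats <- dplyr::bind_cols(feats, assigned)
    } else {
      feats$nodule_class <- character(0)
      feats$occupant <- character(0)
      feats$partial_area_fix_plus <- numeric(0)
      feats$partial_area_fix_minus <- numeric(0)
    }
    nodules <- tibble::tibble(
      nodule_id = if (nrow(feats)) sprintf("%s_d%03d", pid, seq_len(nrow(feats))) else character(0),
      plant_id = rep(pid, nrow(feats)),
      cx = feats$cx, cy = feats$cy, area = feats$area,
      pct_red = feats$pct_red, pct_green = feats$pct_green,
      nodule_class = feats$nodule_class, occupant = feats$occupant,
      partial_area_fix_plus = feats$partial_area_fix_plus,
      partial_area_fix_minus = feats$partial_area_fix_minus
    )
    list(nodules = nodules, ledger = flt$ledger)
  }, error = function(e) {
    stop("detection failed for plant ", pid, ": ", conditionMessage(e),
         call. = FALSE)
  })
  structure(res, class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat("<detection> ", nrow(x$nodules), " nodules retained\n", sep = "")
  print(x$ledger)
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy detection
#' @export
tidy.detection <- function(x, ...) x$nodules

#' @importFrom generics glance
#' @method glance detection
#' @export
glance.detection <- function(x, ...) x$ledger
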