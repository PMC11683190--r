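#' Per-plant sanctions summaries
#'
#' Computes, for every plant in a per-nodule table, the quantities behind the
#' sanctions analysis:
#' * **among-nodule** mode: `z_fix_plus_among` / `z_fix_minus_among`, the mean
#'   total cross-sectional area of single-infection nodules occupied by each
#'   strain;
#' * **within-nodule** mode: `z_fix_plus_within` / `z_fix_minus_within`, the
#'   mean partial nodule area of each strain across mixed-infection nodules;
#' * `strictness_among` and `strictness_within`, each `ln(Z_Fix+ / Z_Fix-)`
#'   for the corresponding pair of Z values.
#'
#' Strictness is only defined when both Z values exist and are positive (at
#' least one nodule in each class); otherwise it is `NA`, never a sentinel
#' number, and such plants are excluded from strictness-based regressions.
#' Non-fluorescent and unknown-occupant nodules never contribute.
#'
#' @param nodules Per-nodule tibble with `plant_id`, `area`, `nodule_class`,
#'   `occupant`, `partial_area_fix_plus`, `partial_area_fix_minus` (the shape
#'   produced by [detect_pipeline()]).
#' @param z_stat Summary statistic for Z, `"mean"` (the definition) or
#'   `"median"` (diagnostic alternative).
#' @return A tibble with one row per plant: counts `n_single_fix_plus`,
#'   `n_single_fix_minus`, `n_mixed`, the four Z values and both strictness
#'   values.
#' @examples
#' nd <- tibble::tibble(
#'   plant_id = "p1", area = c(2.03, 1), nodule_class = "single_red",
#'   occupant = c("fix_plus", "fix_minus"),
#'   partial_area_fix_plus = c(2.03, 0), partial_area_fix_minus = c(0, 1)
#' )
#' summarize_sanctions(nd)$strictness_among  # log(2.03)
#' @export
summarize_sanctions <- function(nodules, z_stat = c("mean", "median")) {
  stopifnot(is.data.frame(nodules))
  z_stat <- match.arg(z_stat)
  zfun <- if (z_stat == "mean") mean else stats::median
  safe_z <- function(x) if (length(x)) zfun(x) else NA_real_
  nodules |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::summarize(
      n_single_fix_plus = sum(.data$occupant == "fix_plus" &
                                .data$nodule_class %in% c("single_red", "single_green")),
      n_single_fix_minus = sum(.data$occupant == "fix_minus" &
                                 .data$nodule_class %in% c("single_red", "single_green")),
      n_mixed = sum(.data$occupant == "mixed"),
      z_fix_plus_among = safe_z(.data$area[.data$occupant == "fix_plus" &
                                             .data$nodule_class %in% c("single_red", "single_green")]),
      z_fix_minus_among = safe_z(.data$area[.data$occupant == "fix_minus" &
                                              .data$nodule_class %in% c("single_red", "single_green")]),
      z_fix_plus_within = safe_z(.data$partial_area_fix_plus[.data$occupant == "mixed"]),
      z_fix_minus_within = safe_z(.data$partial_area_fix_minus[.data$occupant == "mixed"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      strictness_among = strictness(.data$z_fix_plus_among, .data$z_fix_minus_among),
      strictness_within = strictness(.data$z_fix_plus_within, .data$z_fix_minus_within)
    )
}

#' Strictness of sanctions
#'
#' `ln(Z_Fix+ / Z_Fix-)`: positive values mean the plant directs more nodule
#' resources to the nitrogen-fixing strain; values at or below zero mean no
#' sanctioning; `NA` when either Z is missing or non-positive.
#'
#' @param z_fix_plus,z_fix_minus Mean (partial) nodule areas for each strain.
#' @return Numeric vector of strictness values.
#' @export
strictness <- function(z_fix_plus, z_fix_minus) {
  ifelse(!is.na(z_fix_plus) & !is.na(z_fix_minus) &
           z_fix_plus > 0 & z_fix_minus > 0,
         log(z_fix_plus / z_fix_minus), NA_real_)
}

#' Binary sanctioning call
#'
#' A plant is sanctioning iff its strictness is strictly positive; strictness
#' at or below zero means not sanctioning; undefined strictness propagates.
#'
#' @param strictness Numeric vector of strictness values (`NA` = undefined).
#' @return Factor with levels `yes`, `no`, `undefined`.
#' @examples
#' is_sanctioning(c(0.71, 0, -0.2, NA))
#' @export
is_sanctioning <- function(strictness) {
  out <- ifelse(is.na(strictness), "undefined",
                ifelse(strictness > 0, "yes", "no"))
  factor(out, levels = c("yes", "no", "undefined"))
}

#' Marker-effect diagnostics from the reciprocal-labeling design
#'
#' In 1-strain inocula both fluorophores label the same strain, so any
#' red-vs-green difference in detected nodule size or count is a marker
#' (detection) effect, not biology.  This reports those ratios, and emits the
#' Fix+ marker color of every co-inoculated plant (red under version A, green
#' under version B) for use as a covariate in downstream models.
#'
#' @param nodules Per-nodule tibble (as from [detect_pipeline()]) including
#'   single-color classes.
#' @param design Design tibble with `plant_id` and `inoculum`.
#' @return A list of class `marker_report`: `available` (were 1-strain plants
#'   present?), `size_ratio_red_green`, `count_ratio_red_green`, `by_color`
#'   summary tibble, and `covariates` (tibble `plant_id`,
#'   `fix_plus_marker`).
#' @export
marker_balance <- function(nodules, design) {
  stopifnot(is.data.frame(nodules), is.data.frame(design))
  dat <- dplyr::inner_join(nodules, design[, c("plant_id", "inoculum")],
                           by = "plant_id")
  one <- dat[dat$inoculum %in% c("fix_plus", "fix_minus") &
               dat$nodule_class %in% c("single_red", "single_green"), , drop = FALSE]
  if (nrow(one) == 0L) {
    by_color <- tibble::tibble(color = character(), n = integer(),
                               mean_area = numeric())
    size_ratio <- NA_real_; count_ratio <- NA_real_; available <- FALSE
  } else {
    available <- TRUE
    one$color <- ifelse(one$nodule_class == "single_red", "red", "green")
    by_color <- one |>
      dplyr::group_by(.data$color) |>
      dplyr::summarize(n = dplyr::n(), mean_area = mean(.data$area),
                       .groups = "drop")
    gr <- function(col, what) {
      v <- by_color[[what]][by_color$color == col]
      if (length(v)) v else NA_real_
    }
    size_ratio <- gr("red", "mean_area") / gr("green", "mean_area")
    count_ratio <- gr("red", "n") / gr("green", "n")
  }
  co <- design[design$inoculum %in% c("co_A", "co_B"), , drop = FALSE]
  covariates <- tibble::tibble(
    plant_id = co$plant_id,
    fix_plus_marker = ifelse(co$inoculum == "co_A", "red", "green")
  )
  structure(list(available = available,
                 size_ratio_red_green = size_ratio,
                 count_ratio_red_green = count_ratio,
                 by_color = by_color, covariates = covariates),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat("<marker_report>\n")
  if (!x$available) {
    cat("  no 1-strain plants: marker ratios unavailable\n")
  } else {
    cat("  red/green mean-size ratio in 1-strain inocula: ",
        format(x$size_ratio_red_green, digits = 3), "\n", sep = "")
    cat("  red/green count ratio in 1-strain inocula:     ",
        format(x$count_ratio_red_green, digits = 3), "\n", sep = "")
  }
  cat("  ", nrow(x$covariates), " co-inoculated plants with Fix+ marker labels\n",
      sep = "")
  invisible(x)
}
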