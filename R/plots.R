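#' Plot per-treatment sanctions summaries
#'
#' Mean Z (nodule area per occupant strain) with standard-error bars, split by
#' aphid treatment, for the among-nodule or within-nodule mode.  The visual
#' signature of sanctions is the Fix+ bar standing above the Fix- bar; the
#' within-nodule gap is expected to close under aphid exposure.
#'
#' @param sanctions Per-plant sanctions tibble from [summarize_sanctions()].
#' @param design Design tibble with `plant_id` and `aphid`.
#' @param mode `"among"` or `"within"`.
#' @return A ggplot object.
#' @export
plot_sanctions <- function(sanctions, design, mode = c("among", "within")) {
  mode <- match.arg(mode)
  cols <- paste0(c("z_fix_plus_", "z_fix_minus_"), mode)
  dat <- sanctions |>
    dplyr::inner_join(design[, c("plant_id", "aphid")], by = "plant_id") |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "occupant",
                        values_to = "z") |>
    dplyr::mutate(occupant = ifelse(grepl("plus", .data$occupant),
                                    "Fix+", "Fix-")) |>
    dplyr::filter(!is.na(.data$z)) |>
    dplyr::group_by(.data$aphid, .data$occupant) |>
    dplyr::summarize(mean_z = mean(.data$z),
                     se = stats::sd(.data$z) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$aphid, y = .data$mean_z,
                                    fill = .data$occupant)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_z - .data$se, ymax = .data$mean_z + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::scale_fill_manual(values = c("Fix+" = "#1b9e77", "Fix-" = "#d95f02")) +
    ggplot2::labs(x = "aphid treatment",
                  y = if (mode == "among") "mean single-nodule area (mm²)"
                      else "mean partial nodule area (mm²)",
                  fill = "occupant",
                  title = paste0(mode, "-nodule sanctions")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$per_plant,
                  ggplot2::aes(x = .data$n_true, y = .data$n_detected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "true nodule count", y = "detected nodule count",
                  title = sprintf("count recovery (r = %.3f, %d plants)",
                                  object$count_r, nrow(object$per_plant))) +
    ggplot2::theme_minimal()
}

#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$null_stats),
                  ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "#d95f02", linewidth = 1) +
    ggplot2::labs(x = object$statistic, y = "permutations",
                  title = sprintf("observed %.3g, p = %.3g",
                                  object$observed_stat, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
plot.channel_stack <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  maxdn <- 2^x$bit_depth - 1
  for (ch in c("red", "green", "darkfield")) {
    graphics::image(t(x[[ch]][nrow(x[[ch]]):1, ]) / maxdn,
                    col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                    main = ch, useRaster = TRUE)
  }
  invisible(x)
}
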