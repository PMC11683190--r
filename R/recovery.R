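#' Render and detect every plant in a design
#'
#' Convenience wrapper for parameter-recovery studies: samples ground-truth
#' nodules for each plant (unless supplied), renders the mosaic, runs the
#' detection pipeline, and returns the detected nodules joined with the
#' design columns plus the pooled filter ledger and the ground truth.
#'
#' @param design Design tibble from [build_design()] (any subset of rows).
#' @param cfg An [effect_config()].
#' @param det_cfg A [detection_config()]; pixel scale is forced to `cfg`'s.
#' @param truth Optional pre-sampled nodule tibble for these plants.
#' @param seed Optional integer seeding the whole simulate-render-detect run.
#' @return A list: `detected` (tibble with design columns), `truth`,
#'   `ledger` (pooled one-row tibble).
#' @export
detect_design <- function(design, cfg, det_cfg = detection_config(),
                          truth = NULL, seed = NULL) {
  stopifnot(is.data.frame(design), inherits(cfg, "effect_config"))
  if (!is.null(seed)) set.seed(seed)
  det_cfg$pixel_scale <- cfg$pixel_scale
  if (is.null(truth)) truth <- sample_nodule_population(design, cfg)
  det <- vector("list", nrow(design))
  led <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    nd <- truth[truth$plant_id == design$plant_id[i], , drop = FALSE]
    stack <- render_mosaic(nd, cfg)
    res <- detect_pipeline(stack, design[i, ], det_cfg)
    det[[i]] <- res$nodules
    led[[i]] <- res$ledger
  }
  detected <- dplyr::bind_rows(det) |>
    dplyr::left_join(design, by = "plant_id")
  ledger <- dplyr::summarize(dplyr::bind_rows(led),
                             dplyr::across(dplyr::everything(), sum))
  list(detected = detected, truth = truth, ledger = ledger)
}

#' Percent Fix+/Fix- size advantage among detected single-infection nodules
#'
#' Computes `100 * (mean Fix+ area / mean Fix- area - 1)` over detected
#' single-infection nodules, the quantity used to summarize among-nodule
#' sanctions effect sizes.
#'
#' @param detected Detected nodule tibble (with `occupant`, `nodule_class`,
#'   `area`).
#' @return Percent advantage (scalar).
#' @export
pct_advantage_single <- function(detected) {
  singles <- detected[detected$nodule_class %in% c("single_red", "single_green"), ]
  m_fp <- mean(singles$area[singles$occupant == "fix_plus"])
  m_fm <- mean(singles$area[singles$occupant == "fix_minus"])
  100 * (m_fp / m_fm - 1)
}
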