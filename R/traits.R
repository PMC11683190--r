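#' Simulate log colony-forming units for cultured nodules
#'
#' Draws logCFU as a linear function of nodule cross-sectional area plus
#' Gaussian noise: `logCFU = cfu_intercept + cfu_slope * area + N(0, sd)`.
#' When `cfg$cfu_noise_sd` is `NA` (the default) the noise standard deviation
#' is calibrated from the supplied areas so the population correlation between
#' area and logCFU equals `cfg$cfu_r_target`:
#' `sd = |slope| * sd(area) * sqrt(1 / r^2 - 1)`.
#'
#' @param nodule_areas Positive nodule areas in mm^2.
#' @param cfg An [effect_config()].
#' @param seed Optional integer seeding the RNG.
#' @return A numeric vector of logCFU values, one per area.
#' @examples
#' cfg <- effect_config()
#' areas <- rlnorm(200, log(0.2), 0.45)
#' cor(areas, sample_cfu(areas, cfg, seed = 1))
#' @export
sample_cfu <- function(nodule_areas, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "effect_config"))
  if (!is.numeric(nodule_areas) || any(is.na(nodule_areas)) || any(nodule_areas <= 0)) {
    stop("nodule areas must be positive and non-missing", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sd_noise <- cfg$cfu_noise_sd
  if (is.na(sd_noise)) {
    r <- cfg$cfu_r_target
    if (r == 0) {
      # target of exactly zero: drop the slope instead of infinite noise
      return(cfg$cfu_intercept + stats::rnorm(length(nodule_areas), 0, 1))
    }
    sd_noise <- abs(cfg$cfu_slope) * stats::sd(nodule_areas) * sqrt(1 / r^2 - 1)
    if (!is.finite(sd_noise)) sd_noise <- 0
  }
  cfg$cfu_intercept + cfg$cfu_slope * nodule_areas +
    stats::rnorm(length(nodule_areas), 0, sd_noise)
}

#' Simulate plant-level traits
#'
#' Draws shoot fresh mass and SPAD (chlorophyll index) readings from
#' accession-by-inoculum means, and, for plants exposed to virus-carrying
#' (PEMV+) aphids, a virus titer (arbitrary band-intensity units) whose mean
#' depends on the inoculum (Fix+ plants accumulate less virus than Fix-
#' plants) and, on co-inoculated plants, increases with the plant's
#' within-nodule sanctions strictness via `titer_strictness_slope`.
#' Non-nodulating plants share one low shoot-mass mean across all inocula.
#'
#' @param design Design tibble (one row per plant) from [build_design()].
#' @param cfg An [effect_config()].
#' @param strictness_within Optional numeric vector (length `nrow(design)`)
#'   of within-nodule sanctions strictness values; only entries for
#'   co-inoculated plants under PEMV+ aphids are used.  `NA` entries contribute
#'   no strictness term.
#' @param seed Optional integer seeding the RNG.
#' @return A tibble: `plant_id`, `shoot_mass` (g), `spad_before`, `spad_after`,
#'   `pemv_titer` (`NA` unless `aphid == "pemv_plus"`).
#' @export
sample_plant_traits <- function(design, cfg, strictness_within = NULL, seed = NULL) {
  stopifnot(is.data.frame(design), inherits(cfg, "effect_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  if (is.null(strictness_within)) strictness_within <- rep(NA_real_, n)
  if (length(strictness_within) != n) {
    stop("strictness_within must have one entry per design row", call. = FALSE)
  }
  if (any(!is.na(strictness_within) &
          !(design$inoculum %in% c("co_A", "co_B") & design$aphid == "pemv_plus"))) {
    stop("strictness_within may be supplied only for co-inoculated plants ",
         "under PEMV+ aphids", call. = FALSE)
  }
  mass_mean <- vapply(seq_len(n), function(i) {
    cfg$shoot_mass_means[[design$accession[i]]][[design$inoculum[i]]]
  }, numeric(1))
  shoot_mass <- pmax(stats::rnorm(n, mass_mean, cfg$shoot_mass_sd), 0.05)
  spad_before <- stats::rnorm(n, cfg$spad_mean, cfg$spad_sd)
  gain <- cfg$spad_gain[design$inoculum]
  gain[design$accession == "non_nodulating"] <- 0
  spad_after <- spad_before + gain + stats::rnorm(n, 0, cfg$spad_sd / 2)
  titer_mu <- cfg$titer_means[design$inoculum] +
    ifelse(is.na(strictness_within), 0, cfg$titer_strictness_slope * strictness_within)
  pemv_titer <- ifelse(
    design$aphid == "pemv_plus",
    pmax(stats::rnorm(n, titer_mu, cfg$titer_noise_sd), 0),
    NA_real_
  )
  tibble::tibble(
    plant_id = design$plant_id,
    shoot_mass = shoot_mass,
    spad_before = spad_before,
    spad_after = spad_after,
    pemv_titer = pemv_titer
  )
}
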