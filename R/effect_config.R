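#' Generator configuration for the synthetic sanctions experiment
#'
#' `effect_config()` collects every effect size, noise level, geometry setting
#' and seed used by the synthetic-data generator into one validated list.  The
#' defaults encode the study conditions the package is designed to emulate:
#' a 3-accession x 5-inoculum x 3-aphid factorial replicated over 6 blocks,
#' Fix+ single-infection nodules 21% larger than Fix- nodules under 1-strain
#' inoculation and 103% larger under co-inoculation, a 35% Fix+ size boost
#' (and a derived ~20% Fix- size penalty) moving from 1-strain to 2-strain
#' inoculations, 15% mixed-infection nodules, a 39% Fix+ excess in partial
#' nodule area within mixed nodules in the absence of aphids (erased under
#' aphid exposure), 4% non-fluorescent (senescent) nodules, a 2-fold
#' red-over-green channel brightness imbalance, and a nodule-size vs logCFU
#' correlation of 0.37.
#'
#' The three single-nodule size ratios are stored jointly:
#' `ratio_1strain` (Fix+/Fix- mean area under 1-strain inoculation),
#' `ratio_2strain` (same under co-inoculation) and `fix_plus_2strain_boost`
#' (Fix+ mean area in 2-strain relative to 1-strain arms).  The Fix-
#' cross-inoculum multiplier is derived as
#' `ratio_1strain * fix_plus_2strain_boost / ratio_2strain` so the four
#' quantities are always mutually consistent.
#'
#' @param ... Named overrides for any default field (unknown names error).
#' @param seed Integer seed stored with the configuration; identical seed and
#'   configuration reproduce identical designs, nodule tables and images.
#'
#' @return A list of class `effect_config`.
#' @examples
#' cfg <- effect_config(n_blocks = 2, frame_px = 512)
#' cfg$ratio_1strain
#' @export
effect_config <- function(..., seed = 20201221L) {
  cfg <- list(
    # -- design ---------------------------------------------------------------
    n_blocks = 6L,
    accessions = c("wild", "domesticated", "non_nodulating"),
    inocula = c("none", "fix_plus", "fix_minus", "co_A", "co_B"),
    aphids = c("none", "pemv_minus", "pemv_plus"),
    # -- nodule populations ---------------------------------------------------
    mean_nodules_per_plant = c(wild = 70, domesticated = 50, non_nodulating = 0),
    nb_dispersion = 8,
    base_nodule_area = 0.15,          # mm^2; Fix- single nodule, 1-strain arm
    accession_size_mult = c(wild = 0.85, domesticated = 1, non_nodulating = 1),
    size_lognormal_sigma = 0.45,
    ratio_1strain = 1.21,
    ratio_2strain = 2.03,
    fix_plus_2strain_boost = 1.35,
    mixed_area_mult = 1.6,            # mixed nodules run larger than singles
    within_ratio_no_aphid = 1.39,
    within_ratio_aphid = 1.0,
    within_split_concentration = 20,  # Beta concentration of the partial split
    p_mixed = 0.15,
    p_nonfluorescent = 0.04,
    p_touching = 0.05,
    # -- rendering ------------------------------------------------------------
    frame_px = 1024L,
    pixel_scale = 0.01,               # mm per pixel
    bit_depth = 8L,
    green_intensity = 60,
    red_green_brightness_factor = 2,
    intensity_cv = 0.15,              # per-nodule brightness variation
    darkfield_intensity = 70,
    darkfield_background = 15,
    background_level = 8,
    background_noise_sd = 4,
    # -- nodule culturing (CFU) ----------------------------------------------
    cfu_intercept = 5.0,
    cfu_slope = 1.2,                  # logCFU per mm^2
    cfu_noise_sd = NA_real_,          # NA: calibrated from cfu_r_target
    cfu_r_target = 0.37,
    # -- plant traits ---------------------------------------------------------
    shoot_mass_means = list(
      wild           = c(none = 1.5, fix_plus = 3.0, fix_minus = 1.5, co_A = 2.6, co_B = 2.6),
      domesticated   = c(none = 2.0, fix_plus = 4.0, fix_minus = 2.0, co_A = 3.5, co_B = 3.5),
      non_nodulating = c(none = 1.2, fix_plus = 1.2, fix_minus = 1.2, co_A = 1.2, co_B = 1.2)
    ),
    shoot_mass_sd = 0.4,
    spad_mean = 32,
    spad_sd = 3,
    spad_gain = c(none = 0, fix_plus = 6, fix_minus = 0, co_A = 4, co_B = 4),
    titer_means = c(none = 1.3, fix_plus = 0.8, fix_minus = 1.3, co_A = 1.0, co_B = 1.0),
    titer_strictness_slope = 0.8,
    titer_noise_sd = 0.25,
    seed = as.integer(seed)
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("all overrides to effect_config() must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown effect_config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  cfg <- validate_effect_config(cfg)
  class(cfg) <- "effect_config"
  cfg
}

#' Validate an effect configuration
#'
#' Checks probability, positivity and structural invariants; returns the
#' configuration invisibly changed (integer coercions only) or throws an
#' informative error.
#'
#' @param cfg A list of effect-configuration fields.
#' @return The validated configuration.
#' @export
validate_effect_config <- function(cfg) {
  stopifnot(is.list(cfg))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid effect_config: ", msg, call. = FALSE)
  cfg$n_blocks <- as.integer(cfg$n_blocks)
  chk(length(cfg$n_blocks) == 1L && cfg$n_blocks >= 1L, "n_blocks must be >= 1")
  for (p in c("p_mixed", "p_nonfluorescent", "p_touching")) {
    chk(is.numeric(cfg[[p]]) && cfg[[p]] >= 0 && cfg[[p]] <= 1,
        paste(p, "must lie in [0, 1]"))
  }
  chk(cfg$p_mixed + cfg$p_nonfluorescent <= 1,
      "p_mixed + p_nonfluorescent must not exceed 1")
  for (p in c("base_nodule_area", "ratio_1strain", "ratio_2strain",
              "fix_plus_2strain_boost", "mixed_area_mult",
              "within_ratio_no_aphid", "within_ratio_aphid",
              "size_lognormal_sigma", "within_split_concentration",
              "pixel_scale", "red_green_brightness_factor", "green_intensity",
              "nb_dispersion")) {
    chk(is.numeric(cfg[[p]]) && length(cfg[[p]]) == 1L && cfg[[p]] > 0,
        paste(p, "must be a positive scalar"))
  }
  chk(is.numeric(cfg$background_noise_sd) && cfg$background_noise_sd >= 0,
      "background_noise_sd must be >= 0")
  chk(all(cfg$mean_nodules_per_plant >= 0), "mean nodule counts must be >= 0")
  chk(is.numeric(cfg$cfu_r_target) && abs(cfg$cfu_r_target) < 1,
      "cfu_r_target must lie in (-1, 1)")
  chk(cfg$frame_px >= 64, "frame_px must be at least 64")
  chk(cfg$bit_depth %in% c(8L, 16L), "bit_depth must be 8 or 16")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && !is.na(cfg$seed),
      "seed must be a single integer")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @export
print.effect_config <- function(x, ...) {
  cat("<effect_config>\n")
  cat("  design: ", length(x$accessions), " accessions x ", length(x$inocula),
      " inocula x ", length(x$aphids), " aphids x ", x$n_blocks, " blocks\n", sep = "")
  cat("  size ratios: 1-strain ", x$ratio_1strain, ", 2-strain ", x$ratio_2strain,
      ", Fix+ cross-arm boost ", x$fix_plus_2strain_boost, "\n", sep = "")
  cat("  within-nodule ratios: no-aphid ", x$within_ratio_no_aphid,
      ", aphid ", x$within_ratio_aphid, "\n", sep = "")
  cat("  p_mixed ", x$p_mixed, ", p_nonfluorescent ", x$p_nonfluorescent,
      ", p_touching ", x$p_touching, "\n", sep = "")
  cat("  frame ", x$frame_px, "x", x$frame_px, " px @ ", x$pixel_scale,
      " mm/px, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Mean single-nodule area for an occupant in an inoculum arm
#'
#' Internal helper exposing the size model: the Fix- single nodule in a
#' 1-strain inoculation defines the baseline; Fix+ gains `ratio_1strain`;
#' moving to a 2-strain inoculation multiplies Fix+ by
#' `fix_plus_2strain_boost` and Fix- by the derived multiplier
#' `ratio_1strain * fix_plus_2strain_boost / ratio_2strain`.
#'
#' @param occupant `"fix_plus"` or `"fix_minus"`.
#' @param arm `"one_strain"` or `"two_strain"`.
#' @param cfg An [effect_config()].
#' @return Mean nodule cross-sectional area in mm^2 (before accession scaling).
#' @keywords internal
#' @export
mean_single_area <- function(occupant, arm, cfg) {
  base <- cfg$base_nodule_area
  fm_2s_mult <- cfg$ratio_1strain * cfg$fix_plus_2strain_boost / cfg$ratio_2strain
  mult <- dplyr::case_when(
    occupant == "fix_plus" & arm == "one_strain" ~ cfg$ratio_1strain,
    occupant == "fix_plus" & arm == "two_strain" ~ cfg$ratio_1strain * cfg$fix_plus_2strain_boost,
    occupant == "fix_minus" & arm == "one_strain" ~ 1,
    occupant == "fix_minus" & arm == "two_strain" ~ fm_2s_mult,
    TRUE ~ NA_real_
  )
  if (anyNA(mult)) stop("unknown occupant/arm combination", call. = FALSE)
  base * mult
}

#' Write / read an effect configuration as YAML
#'
#' Every field of the configuration, including the seed, round-trips through
#' YAML so a run can be reproduced from its config file alone.
#'
#' @param cfg An [effect_config()].
#' @param path File path for the YAML document.
#' @return `write_effect_config()` returns `path` invisibly;
#'   `read_effect_config()` returns a validated [effect_config()].
#' @export
write_effect_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "effect_config"))
  out <- unclass(cfg)
  # named vectors must become YAML maps, not sequences, to keep their names
  for (f in c("mean_nodules_per_plant", "accession_size_mult", "spad_gain",
              "titer_means")) {
    out[[f]] <- as.list(out[[f]])
  }
  out$shoot_mass_means <- lapply(out$shoot_mass_means, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_effect_config
#' @export
read_effect_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed YAML config '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("malformed YAML config '", path, "': not a mapping", call. = FALSE)
  # yaml flattens named vectors to lists; restore the numeric named vectors
  for (f in c("mean_nodules_per_plant", "accession_size_mult", "spad_gain", "titer_means")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$shoot_mass_means)) {
    raw$shoot_mass_means <- lapply(raw$shoot_mass_means, unlist)
  }
  seed <- if (is.null(raw$seed)) 20201221L else raw$seed
  raw$seed <- NULL
  do.call(effect_config, c(raw, list(seed = seed)))
}
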