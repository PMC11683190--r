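#' Simulate a complete experiment (tables only)
#'
#' Generates the design, ground-truth nodule populations and plant traits for
#' one seeded run of the factorial experiment, without rendering images.
#' Within-nodule sanctions strictness feeds the virus-titer model for
#' co-inoculated plants under PEMV+ aphids, computed here from the
#' ground-truth partial areas.
#'
#' @param cfg An [effect_config()].
#' @return A list with tibbles `design`, `nodules` and `traits`.
#' @export
simulate_experiment <- function(cfg = effect_config()) {
  stopifnot(inherits(cfg, "effect_config"))
  set.seed(cfg$seed)
  design <- build_design(cfg$n_blocks, cfg$accessions, cfg$inocula, cfg$aphids)
  nodules <- sample_nodule_population(design, cfg)
  strict <- truth_strictness_within(nodules, design)
  traits <- sample_plant_traits(design, cfg, strictness_within = strict)
  list(design = design, nodules = nodules, traits = traits)
}

# Within-nodule strictness from ground-truth partial areas, one value per
# design row; NA except for co-inoculated PEMV+ plants with mixed nodules.
truth_strictness_within <- function(nodules, design) {
  vapply(seq_len(nrow(design)), function(i) {
    if (!(design$inoculum[i] %in% c("co_A", "co_B")) ||
        design$aphid[i] != "pemv_plus") return(NA_real_)
    nd <- nodules[nodules$plant_id == design$plant_id[i] &
                    nodules$occupancy_kind == "mixed", , drop = FALSE]
    if (nrow(nd) == 0L) return(NA_real_)
    strictness(mean(nd$true_partial_area_fix_plus),
               mean(nd$true_partial_area_fix_minus))
  }, numeric(1))
}

#' Run the full pipeline: simulate, render, detect, summarize, test
#'
#' Executes every stage in order from a YAML configuration: builds the design;
#' samples ground-truth nodules; renders and writes one 3-page TIFF per plant
#' (named `<plant_id>.tif`); re-reads each image and runs the detection
#' pipeline; summarizes per-plant sanctions; samples plant traits (titer
#' coupled to the *detected* within-nodule strictness); runs the headline
#' permutation inferences (Fix+ vs Fix- occupant contrasts for total areas of
#' single-infection nodules and partial areas of mixed nodules, within each
#' aphid treatment, Holm-adjusted; and the strictness-titer association with
#' the Fix+ marker color as stratifying covariate); and writes all tables, a
#' plain-text report and a YAML run manifest.
#'
#' @param config_path Path to a YAML file of [effect_config()] fields.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @param n_blocks Optional integer overriding the config block count.
#' @param n_perm Permutations for the inference stage.
#' @param det_cfg A [detection_config()]; its pixel scale is forced to the
#'   generator's.
#' @return A list of class `run_manifest` (invisibly): config snapshot, seed,
#'   package version, per-stage output paths and row counts, and the pooled
#'   filter ledger.
#' @export
full_run <- function(config_path, out_dir, seed = NULL, n_blocks = NULL,
                     n_perm = 999, det_cfg = detection_config()) {
  cfg <- read_effect_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(n_blocks)) {
    cfg$n_blocks <- as.integer(n_blocks)
    cfg <- validate_effect_config(cfg)
  }
  det_cfg$pixel_scale <- cfg$pixel_scale
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)

  set.seed(cfg$seed)
  design <- build_design(cfg$n_blocks, cfg$accessions, cfg$inocula, cfg$aphids)
  nodules <- sample_nodule_population(design, cfg)

  detected <- vector("list", nrow(design))
  ledgers <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    pid <- design$plant_id[i]
    nd <- nodules[nodules$plant_id == pid, , drop = FALSE]
    stack <- render_mosaic(nd, cfg)
    ipath <- file.path(img_dir, paste0(pid, ".tif"))
    write_channel_stack(stack, ipath)
    res <- detect_pipeline(read_channel_stack(ipath), design[i, ], det_cfg)
    detected[[i]] <- res$nodules
    ledgers[[i]] <- res$ledger
  }
  detected <- dplyr::bind_rows(detected)
  ledger <- dplyr::summarize(dplyr::bind_rows(ledgers),
                             dplyr::across(dplyr::everything(), sum))
  sanctions <- summarize_sanctions(detected)
  sanctions <- dplyr::left_join(design["plant_id"], sanctions, by = "plant_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                ~ tidyr::replace_na(.x, 0L)))

  strict <- sanctions$strictness_within
  strict[!(design$inoculum %in% c("co_A", "co_B") & design$aphid == "pemv_plus")] <- NA_real_
  traits <- sample_plant_traits(design, cfg, strictness_within = strict)

  results <- headline_inferences(detected, design, sanctions, traits,
                                 n_perm = n_perm, seed = cfg$seed)

  paths <- list(
    design = file.path(out_dir, "design.csv"),
    nodule_truth = file.path(out_dir, "nodule_truth.csv"),
    nodules = file.path(out_dir, "nodules_detected.csv"),
    sanctions = file.path(out_dir, "sanctions.csv"),
    traits = file.path(out_dir, "traits.csv"),
    ledger = file.path(out_dir, "filter_ledger.csv"),
    results = file.path(out_dir, "results.csv"),
    config = file.path(out_dir, "config.yml")
  )
  write_table_csv(design, paths$design, "design")
  write_table_csv(nodules, paths$nodule_truth, "nodule_truth")
  write_table_csv(detected, paths$nodules, "nodules")
  write_table_csv(sanctions, paths$sanctions, "sanctions")
  write_table_csv(traits, paths$traits, "traits")
  write_table_csv(ledger, paths$ledger, "ledger")
  write_table_csv(results, paths$results, "results")
  write_effect_config(cfg, paths$config)

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("nodulr")),
    seed = cfg$seed,
    n_perm = n_perm,
    config = unclass(cfg),
    detection = unclass(det_cfg),
    stages = c("simulate", "render", "detect", "sanctions", "stats"),
    outputs = lapply(names(paths), function(nm) {
      rows <- switch(nm, design = nrow(design), nodule_truth = nrow(nodules),
                     nodules = nrow(detected), sanctions = nrow(sanctions),
                     traits = nrow(traits), ledger = 1L, results = nrow(results),
                     config = NA_integer_)
      list(name = nm, path = basename(paths[[nm]]), rows = rows)
    }),
    n_images = nrow(design),
    ledger = as.list(ledger)
  ), class = "run_manifest")
  yaml::write_yaml(unclass(manifest), file.path(out_dir, "manifest.yml"))
  write_run_report(file.path(out_dir, "report.txt"), design, ledger,
                   sanctions, results)
  invisible(manifest)
}

# Headline permutation inferences on the detected tables.
headline_inferences <- function(detected, design, sanctions, traits,
                                n_perm, seed) {
  dat <- dplyr::inner_join(detected, design, by = "plant_id")
  co <- dat[dat$inoculum %in% c("co_A", "co_B"), , drop = FALSE]
  rows <- list()
  for (aph in unique(design$aphid)) {
    singles <- co[co$aphid == aph & co$occupant %in% c("fix_plus", "fix_minus") &
                    co$nodule_class %in% c("single_red", "single_green"), , drop = FALSE]
    rows[[paste0("among_", aph)]] <- try_contrast(
      singles, sprintf("among-nodule area, Fix+ vs Fix- (%s aphids)", aph),
      n_perm, seed)
    mixed <- co[co$aphid == aph & co$occupant == "mixed", , drop = FALSE]
    if (nrow(mixed)) {
      long <- tidyr::pivot_longer(
        mixed, c("partial_area_fix_plus", "partial_area_fix_minus"),
        names_to = "occ", values_to = "partial")
      long$occ <- sub("partial_area_", "", long$occ)
      long$area <- long$partial
      long$occupant <- long$occ
      rows[[paste0("within_", aph)]] <- try_contrast(
        long, sprintf("within-nodule partial area, Fix+ vs Fix- (%s aphids)", aph),
        n_perm, seed)
    }
  }
  res <- dplyr::bind_rows(Filter(Negate(is.null), rows))
  if (nrow(res)) res$adjusted_p <- holm_adjust(res$p)

  assoc <- tryCatch({
    plants <- design |>
      dplyr::left_join(sanctions, by = "plant_id") |>
      dplyr::left_join(traits, by = "plant_id") |>
      dplyr::filter(.data$inoculum %in% c("co_A", "co_B"),
                    .data$aphid == "pemv_plus") |>
      dplyr::mutate(fix_plus_marker = ifelse(.data$inoculum == "co_A", "red", "green"))
    a <- strictness_titer_association(plants, strictness_within, pemv_titer,
                                      fix_plus_marker, n_perm = n_perm, seed = seed)
    tibble::tibble(contrast = "PEMV titer ~ within-nodule strictness",
                   estimate = a$slope, p = a$p_value, adjusted_p = a$p_value,
                   n = a$n, seed = seed)
  }, error = function(e) NULL)
  dplyr::bind_rows(res, assoc)
}

try_contrast <- function(nodule_rows, label, n_perm, seed) {
  tryCatch({
    pt <- cluster_permutation_contrast(nodule_rows, area, occupant, plant_id,
                                       n_perm = n_perm, seed = seed)
    # classes are sorted: fix_minus, fix_plus; report Fix+ minus Fix-
    tibble::tibble(contrast = label, estimate = -pt$observed_stat,
                   p = pt$p_value, adjusted_p = NA_real_,
                   n = pt$n, seed = seed)
  }, error = function(e) NULL)
}

write_run_report <- function(path, design, ledger, sanctions, results) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("nodulr full-run report")
  w("======================")
  w("plants: ", nrow(design))
  w("filter ledger: initial ", ledger$n_initial_features,
    ", holes ", ledger$n_holes_removed, ", below-min ", ledger$n_below_min,
    ", above-max ", ledger$n_above_max, ", retained ", ledger$n_retained)
  def <- sanctions[!is.na(sanctions$strictness_among), , drop = FALSE]
  w("plants with defined among-nodule strictness: ", nrow(def),
    " (mean ", format(mean(def$strictness_among), digits = 3), ")")
  defw <- sanctions[!is.na(sanctions$strictness_within), , drop = FALSE]
  w("plants with defined within-nodule strictness: ", nrow(defw),
    if (nrow(defw)) paste0(" (mean ", format(mean(defw$strictness_within), digits = 3), ")") else "")
  w("")
  w("headline inferences:")
  for (i in seq_len(nrow(results))) {
    w("  ", results$contrast[i], ": estimate ",
      format(results$estimate[i], digits = 3), ", p ",
      format(results$p[i], digits = 3), ", Holm-adjusted ",
      format(results$adjusted_p[i], digits = 3))
  }
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> nodulr ", x$package_version, ", seed ", x$seed, "\n", sep = "")
  cat("  stages: ", paste(x$stages, collapse = " -> "), "\n", sep = "")
  cat("  images: ", x$n_images, "\n", sep = "")
  for (o in x$outputs) {
    cat("  ", format(o$name, width = 12), o$path,
        if (!is.na(o$rows)) paste0(" (", o$rows, " rows)") else "", "\n", sep = "")
  }
  invisible(x)
}
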