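#' Sample ground-truth nodule populations for a set of plants
#'
#' Draws, for every plant in `design`, a nodule count (negative binomial around
#' the accession-specific mean), an occupancy kind for each nodule
#' (single-infection Fix+, single-infection Fix-, mixed-infection, or
#' non-fluorescent/senescent), a total cross-sectional area (log-normal with
#' multiplicative occupant-by-inoculum effects), a within-nodule partial-area
#' split for mixed nodules (Beta-distributed around the configured Fix+/Fix-
#' ratio, which depends on the plant's aphid treatment), fluorophore colors
#' under the plant's labeling scheme, and pixel-space centers along simulated
#' root curves (with a configurable probability of touching-nodule pairs that
#' reproduce the merge artifact of edge-to-edge nodules).
#'
#' Uninoculated and non-nodulating plants receive no nodules.  Mixed-infection
#' nodules occur only on plants whose inoculum carries both a red and a green
#' strain.  On 1-strain plants the red/green color of each nodule is assigned
#' 50:50 independently of size, so fluorophore detection differences cannot
#' masquerade as occupant effects.
#'
#' @param design A design tibble from [build_design()] (any subset of rows).
#' @param cfg An [effect_config()].
#' @param counts Optional integer vector (length `nrow(design)`) overriding the
#'   random per-plant nodule counts; used by validation benchmarks.
#' @param place If `FALSE`, skip pixel-space placement (centers become `NA`);
#'   useful for distribution studies that never render images and may use
#'   populations denser than one frame can hold.
#' @param seed Optional integer; if supplied, seeds the RNG before sampling.
#' @return A tibble with one row per nodule: identifiers, treatment columns,
#'   `occupancy_kind`, `true_total_area`, `true_partial_area_fix_plus`,
#'   `true_partial_area_fix_minus` (mm^2; partials sum to the total for mixed
#'   nodules, exactly one is positive for singles, both zero for
#'   non-fluorescent), `color`, `color_red_strain`, `color_green_strain`,
#'   `render_style`, `touching_partner`, and pixel geometry `cx`, `cy`,
#'   `radius_px`.
#' @export
sample_nodule_population <- function(design, cfg, counts = NULL, place = TRUE,
                                     seed = NULL) {
  stopifnot(is.data.frame(design), inherits(cfg, "effect_config"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(counts) && length(counts) != nrow(design)) {
    stop("counts must have one entry per design row", call. = FALSE)
  }
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    out[[i]] <- sample_plant_nodules(design[i, ], cfg,
                                     count = if (is.null(counts)) NULL else counts[[i]],
                                     place = place)
  }
  dplyr::bind_rows(out)
}

# One plant's nodule population (count, kinds, sizes, splits, colors, layout).
sample_plant_nodules <- function(plant, cfg, count = NULL, place = TRUE) {
  empty <- nodule_tibble_prototype()
  cols <- inoculum_colors(plant$inoculum)
  if (plant$accession == "non_nodulating" || plant$inoculum == "none") {
    return(empty)
  }
  mu_n <- cfg$mean_nodules_per_plant[[plant$accession]]
  n <- if (!is.null(count)) as.integer(count) else
    stats::rnbinom(1L, mu = mu_n, size = cfg$nb_dispersion)
  if (is.na(n) || n <= 0L) return(empty)

  arm <- if (cols$both_strains) "two_strain" else "one_strain"
  acc_mult <- cfg$accession_size_mult[[plant$accession]]
  sig <- cfg$size_lognormal_sigma

  # occupancy kinds
  if (cols$both_strains) {
    p_single <- (1 - cfg$p_mixed - cfg$p_nonfluorescent) / 2
    kinds <- sample(
      c("single_fix_plus", "single_fix_minus", "mixed", "nonfluorescent"),
      n, replace = TRUE,
      prob = c(p_single, p_single, cfg$p_mixed, cfg$p_nonfluorescent)
    )
  } else {
    single_kind <- paste0("single_", cols$red)  # both colors carry this strain
    kinds <- sample(
      c(single_kind, "nonfluorescent"), n, replace = TRUE,
      prob = c(1 - cfg$p_nonfluorescent, cfg$p_nonfluorescent)
    )
  }

  # total areas: log-normal with the configured mean for each kind
  mean_area <- vapply(kinds, function(k) {
    switch(k,
      single_fix_plus  = mean_single_area("fix_plus", arm, cfg),
      single_fix_minus = mean_single_area("fix_minus", arm, cfg),
      mixed            = cfg$base_nodule_area * cfg$mixed_area_mult,
      nonfluorescent   = cfg$base_nodule_area * 0.7
    )
  }, numeric(1)) * acc_mult
  area <- stats::rlnorm(n, meanlog = log(mean_area) - sig^2 / 2, sdlog = sig)

  # within-nodule split for mixed nodules
  r_within <- if (plant$aphid == "none") cfg$within_ratio_no_aphid else cfg$within_ratio_aphid
  mu_split <- r_within / (1 + r_within)
  nu <- cfg$within_split_concentration
  frac_fp <- ifelse(kinds == "mixed",
                    stats::rbeta(n, mu_split * nu, (1 - mu_split) * nu), NA_real_)
  partial_fp <- dplyr::case_when(
    kinds == "mixed" ~ frac_fp * area,
    kinds == "single_fix_plus" ~ area,
    TRUE ~ 0
  )
  partial_fm <- dplyr::case_when(
    kinds == "mixed" ~ area - frac_fp * area,
    kinds == "single_fix_minus" ~ area,
    TRUE ~ 0
  )

  # fluorophore color of single-infection nodules
  color <- rep(NA_character_, n)
  single <- kinds %in% c("single_fix_plus", "single_fix_minus")
  if (cols$both_strains) {
    strain <- sub("^single_", "", kinds[single])
    color[single] <- ifelse(strain == cols$red, "red", "green")
  } else {
    color[single] <- sample(c("red", "green"), sum(single), replace = TRUE)
  }
  style <- ifelse(kinds == "mixed",
                  sample(c("sectors", "patches"), n, replace = TRUE), NA_character_)

  radius_px <- sqrt((area / cfg$pixel_scale^2) / pi)
  touching <- stats::runif(n) < cfg$p_touching
  touching[1] <- FALSE
  layout <- if (place) {
    place_nodules(radius_px, touching, cfg$frame_px, plant$plant_id)
  } else {
    list(cx = rep(NA_real_, n), cy = rep(NA_real_, n),
         partner = rep(NA_integer_, n))
  }

  ids <- sprintf("%s_n%03d", plant$plant_id, seq_len(n))
  tibble::tibble(
    nodule_id = ids,
    plant_id = plant$plant_id,
    block = plant$block,
    accession = plant$accession,
    inoculum = plant$inoculum,
    aphid = plant$aphid,
    occupancy_kind = kinds,
    true_total_area = area,
    true_partial_area_fix_plus = partial_fp,
    true_partial_area_fix_minus = partial_fm,
    color = color,
    color_red_strain = cols$red,
    color_green_strain = cols$green,
    render_style = style,
    touching_partner = ifelse(is.na(layout$partner), NA_character_, ids[layout$partner]),
    cx = layout$cx,
    cy = layout$cy,
    radius_px = radius_px
  )
}

nodule_tibble_prototype <- function() {
  tibble::tibble(
    nodule_id = character(), plant_id = character(), block = integer(),
    accession = character(), inoculum = character(), aphid = character(),
    occupancy_kind = character(), true_total_area = numeric(),
    true_partial_area_fix_plus = numeric(), true_partial_area_fix_minus = numeric(),
    color = character(), color_red_strain = character(),
    color_green_strain = character(), render_style = character(),
    touching_partner = character(), cx = numeric(), cy = numeric(),
    radius_px = numeric()
  )
}

# Place nodule centers along simulated root curves inside the frame.
# Touching nodules are set edge-to-edge with a previously placed partner;
# all other pairs keep a small clearance.  Errors if the frame is overcrowded.
place_nodules <- function(radius_px, touching, frame, plant_id,
                          clearance = 3, max_attempts = 1000L) {
  n <- length(radius_px)
  cx <- cy <- rep(NA_real_, n)
  partner <- rep(NA_integer_, n)
  if (n == 0L) return(list(cx = cx, cy = cy, partner = partner))
  curves <- root_curves(max(3L, ceiling(n / 12)), frame)
  for (i in seq_len(n)) {
    r <- radius_px[i]
    placed <- which(!is.na(cx[seq_len(i - 1)]))
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      if (touching[i] && length(placed) && a <= 0.5 * max_attempts) {
        j <- placed[sample.int(length(placed), 1L)]
        ang <- stats::runif(1, 0, 2 * pi)
        d <- (r + radius_px[j]) - 0.5   # just inside edge-to-edge so masks touch
        cand <- c(cx[j] + d * cos(ang), cy[j] + d * sin(ang))
        skip <- j
      } else if (a <= 0.6 * max_attempts) {
        cv <- curves[[sample.int(length(curves), 1L)]]
        t <- stats::runif(1)
        cand <- c(
          (1 - t)^2 * cv$p0[1] + 2 * (1 - t) * t * cv$p1[1] + t^2 * cv$p2[1],
          (1 - t)^2 * cv$p0[2] + 2 * (1 - t) * t * cv$p1[2] + t^2 * cv$p2[2]
        ) + stats::rnorm(2, 0, 20)
        skip <- 0L
      } else {
        # dense roots: fall back to uniform placement anywhere in the frame
        cand <- stats::runif(2, r + 2, frame - r - 1)
        skip <- 0L
      }
      if (cand[1] < r + 2 || cand[1] > frame - r - 1 ||
          cand[2] < r + 2 || cand[2] > frame - r - 1) next
      if (length(placed)) {
        others <- setdiff(placed, skip)
        if (length(others)) {
          d2 <- (cx[others] - cand[1])^2 + (cy[others] - cand[2])^2
          if (any(d2 < (radius_px[others] + r + clearance)^2)) next
        }
      }
      cx[i] <- cand[1]; cy[i] <- cand[2]
      if (touching[i] && length(placed)) partner[i] <- skip
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("cannot place ", n, " nodules without excessive overlap for plant ",
           plant_id, " (frame ", frame, "x", frame, " px)", call. = FALSE)
    }
  }
  list(cx = cx, cy = cy, partner = partner)
}

# Quadratic Bezier "roots" spanning the frame top to bottom.
root_curves <- function(k, frame) {
  lapply(seq_len(k), function(i) {
    list(
      p0 = c(stats::runif(1, 0.1, 0.9) * frame, stats::runif(1, 0, 0.15) * frame),
      p1 = c(stats::runif(1, 0.05, 0.95) * frame, stats::runif(1, 0.3, 0.7) * frame),
      p2 = c(stats::runif(1, 0.1, 0.9) * frame, stats::runif(1, 0.85, 1) * frame)
    )
  })
}
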