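# Shared fixtures and independent test-side oracles.  Everything here is
# generated in code; no binary fixtures.

# A small, fast configuration for unit tests (full-size runs live in the
# acceptance suite).
tiny_cfg <- function(...) {
  effect_config(
    frame_px = 256L,
    mean_nodules_per_plant = c(wild = 12, domesticated = 10, non_nodulating = 0),
    ...
  )
}

# Build a one-row ground-truth nodule tibble by hand (for rendering tests).
manual_nodule <- function(cfg, kind = "single_fix_plus", area = 0.15,
                          frac_fp = NA, color = "red", style = NA_character_,
                          cx = NULL, cy = NULL, inoculum = "co_A",
                          plant_id = "B1_wild_co_A_none", id = "n001") {
  cols <- inoculum_colors(inoculum)
  if (is.null(cx)) cx <- cfg$frame_px / 2
  if (is.null(cy)) cy <- cfg$frame_px / 2
  pfp <- switch(kind, single_fix_plus = area, mixed = frac_fp * area, 0)
  pfm <- switch(kind, single_fix_minus = area, mixed = (1 - frac_fp) * area, 0)
  tibble::tibble(
    nodule_id = id, plant_id = plant_id, block = 1L, accession = "wild",
    inoculum = inoculum, aphid = "none", occupancy_kind = kind,
    true_total_area = area, true_partial_area_fix_plus = pfp,
    true_partial_area_fix_minus = pfm,
    color = if (kind %in% c("single_fix_plus", "single_fix_minus")) color else NA_character_,
    color_red_strain = cols$red, color_green_strain = cols$green,
    render_style = style, touching_partner = NA_character_,
    cx = cx, cy = cy, radius_px = sqrt((area / cfg$pixel_scale^2) / pi)
  )
}

# Rasterize a disc into a matrix (independent of the package's renderer).
disc_mat <- function(f, cx, cy, r, val = 200, base = 0) {
  m <- matrix(base, f, f)
  col <- matrix(rep(seq_len(f), each = f), f, f)   # x
  row <- matrix(rep(seq_len(f), times = f), f, f)  # y
  m[(col - cx)^2 + (row - cy)^2 <= r^2] <- val
  m
}

make_stack <- function(red, green = NULL, dark = NULL, pixel_scale = 0.01) {
  f <- nrow(red)
  if (is.null(green)) green <- matrix(0, f, f)
  if (is.null(dark)) dark <- matrix(0, f, f)
  channel_stack(red, green, dark, pixel_scale = pixel_scale)
}

# Convert ground-truth nodules to the detected-nodule table shape, for
# testing sanctions metrics directly against the generator.
truth_as_detected <- function(nod) {
  cls <- dplyr::case_when(
    nod$occupancy_kind == "mixed" ~ "mixed_color",
    nod$occupancy_kind == "nonfluorescent" ~ "nonfluorescent",
    nod$color == "red" ~ "single_red",
    TRUE ~ "single_green"
  )
  occ <- dplyr::case_when(
    nod$occupancy_kind == "single_fix_plus" ~ "fix_plus",
    nod$occupancy_kind == "single_fix_minus" ~ "fix_minus",
    nod$occupancy_kind == "mixed" ~ "mixed",
    TRUE ~ "unknown"
  )
  tibble::tibble(
    nodule_id = nod$nodule_id, plant_id = nod$plant_id,
    cx = nod$cx, cy = nod$cy, area = nod$true_total_area,
    pct_red = NA_real_, pct_green = NA_real_,
    nodule_class = cls, occupant = occ,
    partial_area_fix_plus = nod$true_partial_area_fix_plus,
    partial_area_fix_minus = nod$true_partial_area_fix_minus
  )
}

# ---- independent flood-fill oracle (8-connected components, 4-connected
# holes), used to cross-check the labeling implementation ------------------
oracle_label8 <- function(fg) {
  n <- nrow(fg); m <- ncol(fg)
  lab <- matrix(0L, n, m)
  cur <- 0L
  for (j in seq_len(m)) for (i in seq_len(n)) {
    if (fg[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= m &&
              fg[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

oracle_count_holes <- function(fg) {
  n <- nrow(fg); m <- ncol(fg)
  seen <- matrix(FALSE, n, m)
  # flood 4-connected background from every border cell
  queue <- list()
  for (i in seq_len(n)) for (j in c(1L, m)) {
    if (!fg[i, j]) queue[[length(queue) + 1L]] <- c(i, j)
  }
  for (j in seq_len(m)) for (i in c(1L, n)) {
    if (!fg[i, j]) queue[[length(queue) + 1L]] <- c(i, j)
  }
  for (q in queue) seen[q[1], q[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- p[1] + d[1]; jj <- p[2] + d[2]
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m &&
          !fg[ii, jj] && !seen[ii, jj]) {
        seen[ii, jj] <- TRUE
        queue[[length(queue) + 1L]] <- c(ii, jj)
      }
    }
  }
  # remaining unseen background cells form the holes; count 4-conn components
  holes <- 0L
  for (j in seq_len(m)) for (i in seq_len(n)) {
    if (!fg[i, j] && !seen[i, j]) {
      holes <- holes + 1L
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- p[1] + d[1]; jj <- p[2] + d[2]
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= m &&
              !fg[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  holes
}

# Exhaustive within-plant relabeling oracle for the cluster permutation test.
oracle_exact_contrast_p <- function(values, labels, plants) {
  classes <- sort(unique(labels))
  split_i <- split(seq_along(values), plants)
  stat <- function(lab) {
    pm <- vapply(split_i, function(i) {
      c(mean(values[i][lab[i] == classes[1]]), mean(values[i][lab[i] == classes[2]]))
    }, numeric(2))
    mean(pm[1, !is.nan(pm[1, ])]) - mean(pm[2, !is.nan(pm[2, ])])
  }
  obs <- stat(labels)
  per_plant <- lapply(split_i, function(i) {
    nA <- sum(labels[i] == classes[1])
    combn(length(i), nA, simplify = FALSE)  # nA = 0 or n gives one fixed option
  })
  grids <- expand.grid(lapply(per_plant, seq_along))
  null <- apply(grids, 1, function(sel) {
    lab <- labels
    for (k in seq_along(split_i)) {
      i <- split_i[[k]]
      lab[i] <- classes[2]
      lab[i[per_plant[[k]][[sel[k]]]]] <- classes[1]
    }
    stat(lab)
  })
  list(observed = obs, null = null,
       p = sum(abs(null) >= abs(obs) - 1e-12) / length(null))
}
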