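dc <- detection_config()

test_that("segmentation finds discs with the right pixel support", {
  # blank image
  st <- make_stack(matrix(0, 128, 128))
  seg <- segment_features(st, dc)
  expect_equal(nrow(seg$features), 0)
  # one red disc of radius 20: ~ pi r^2 pixels
  st1 <- make_stack(disc_mat(128, 64, 64, 20, 200))
  seg1 <- segment_features(st1, dc)
  expect_equal(nrow(seg1$features), 1)
  expect_equal(seg1$features$n_pixels, pi * 20^2, tolerance = 0.02)
  # two overlapping discs in the same channel form one feature
  red2 <- pmax(disc_mat(128, 50, 64, 15, 200), disc_mat(128, 70, 64, 15, 200))
  expect_equal(nrow(segment_features(make_stack(red2), dc)$features), 1)
  # discs in different channels that touch also merge (union foreground)
  st3 <- make_stack(disc_mat(128, 50, 64, 15, 200),
                    disc_mat(128, 80, 64, 15, 200))
  expect_equal(nrow(segment_features(st3, dc)$features), 1)
})

test_that("foreground connectivity is 8-connected", {
  red <- matrix(0, 16, 16)
  red[cbind(c(4, 5, 6), c(4, 5, 6))] <- 200  # diagonal chain
  seg <- segment_features(make_stack(red), dc)
  expect_equal(nrow(seg$features), 1)
  expect_equal(seg$features$n_pixels, 3)
})

test_that("degenerate thresholds are refused", {
  st <- make_stack(matrix(10, 32, 32))
  expect_error(segment_features(st, detection_config(red_threshold = 0,
                                                     green_threshold = 0)),
               "degenerate")
})

test_that("hole removal fills enclosed regions and counts them", {
  # solid disc: nothing to fill
  seg <- segment_features(make_stack(disc_mat(64, 32, 32, 12, 200)), dc)
  fill <- remove_holes(seg$labels)
  expect_equal(fill$n_holes_removed, 0)
  expect_identical(fill$labels, seg$labels)
  # annulus: one hole, filled to the full disc
  ring <- disc_mat(64, 32, 32, 14, 200)
  ring[disc_mat(64, 32, 32, 6, 1) == 1] <- 0
  segr <- segment_features(make_stack(ring), dc)
  fillr <- remove_holes(segr$labels)
  expect_equal(fillr$n_holes_removed, 1)
  expect_equal(sum(fillr$labels > 0), sum(disc_mat(64, 32, 32, 14, 1) == 1))
  # two nested rings: two enclosed background regions
  nest <- disc_mat(64, 32, 32, 20, 200)
  nest[disc_mat(64, 32, 32, 16, 1) == 1] <- 0
  nest[disc_mat(64, 32, 32, 12, 1) == 1] <- 200
  nest[disc_mat(64, 32, 32, 6, 1) == 1] <- 0
  segn <- segment_features(make_stack(nest), dc)
  filln <- remove_holes(segn$labels)
  expect_equal(filln$n_holes_removed, 2)
})

test_that("labeling and hole counts agree with a flood-fill oracle on small images", {
  set.seed(77)
  for (rep in 1:8) {
    fg <- matrix(stats::runif(48 * 48) < 0.35, 48, 48)
    lab <- nodulr:::label_components_8(fg)
    oracle <- oracle_label8(fg)
    expect_equal(max(lab), max(oracle))
    expect_equal(sort(tabulate(lab[lab > 0])), sort(tabulate(oracle[oracle > 0])))
    expect_equal(remove_holes(lab)$n_holes_removed, oracle_count_holes(fg))
  }
})

test_that("size filtering keeps the ledger in exact balance", {
  feats <- tibble::tibble(feature_id = 1:3,
                          n_pixels = as.integer(c(0.5, 1.5, 2 * 12 / 0.05) *
                                                  dc$min_area / dc$pixel_scale^2))
  res <- filter_by_size(feats, dc, n_holes_removed = 0L)
  expect_equal(unlist(res$ledger),
               c(n_initial_features = 3, n_holes_removed = 0, n_below_min = 1,
                 n_above_max = 1, n_retained = 1))
  expect_equal(res$features$feature_id, 2L)
  # no-op filter retains everything
  all_cfg <- detection_config(min_area = 0, max_area = Inf)
  expect_equal(filter_by_size(feats, all_cfg)$ledger$n_retained, 3L)
  # raising min_area never increases retention (monotonicity)
  set.seed(5)
  px <- tibble::tibble(feature_id = 1:50,
                       n_pixels = as.integer(stats::rlnorm(50, 7, 1)))
  kept <- vapply(c(0.01, 0.05, 0.1, 0.3),
                 function(m) filter_by_size(px, detection_config(min_area = m))$ledger$n_retained,
                 integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("occupancy percentages reflect channel support", {
  f <- 96
  half_red <- disc_mat(f, 48, 48, 20, 200)
  half_red[, 49:f] <- 0
  half_green <- disc_mat(f, 48, 48, 20, 200)
  half_green[, 1:48] <- 0
  st <- make_stack(half_red, half_green)
  seg <- segment_features(st, dc)
  occ <- quantify_occupancy(seg$labels, st, 60, 30)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$pct_red, 50, tolerance = 0.06)
  expect_equal(occ$pct_green, 50, tolerance = 0.06)
  # red-only nodule
  str <- make_stack(disc_mat(f, 48, 48, 15, 200))
  segr <- segment_features(str, dc)
  occr <- quantify_occupancy(segr$labels, str, 60, 30)
  expect_equal(c(occr$pct_red, occr$pct_green), c(100, 0))
})

test_that("nodule classes follow the minor-fraction rule", {
  expect_equal(classify_nodule(95, 5, dc), "single_red")
  expect_equal(classify_nodule(60, 40, dc), "mixed_color")
  expect_equal(classify_nodule(0, 0, dc), "nonfluorescent")
  expect_equal(classify_nodule(5, 95, dc), "single_green")
  expect_equal(classify_nodule(10, 10, dc), "mixed_color")  # boundary: >= cutoff
  expect_error(classify_nodule(120, 0, dc), "\\[0, 100\\]")
  # raising the cutoff never increases mixed calls
  set.seed(8)
  pr <- stats::runif(200, 0, 100); pg <- stats::runif(200, 0, 100)
  n_mixed <- vapply(c(0.05, 0.1, 0.2, 0.4), function(mmf) {
    sum(classify_nodule(pr, pg, detection_config(mixed_minor_fraction = mmf)) ==
          "mixed_color")
  }, integer(1))
  expect_true(all(diff(n_mixed) <= 0))
})

test_that("colors map to strains per the labeling scheme", {
  # single_red is Fix+ under version A but Fix- under version B
  expect_equal(assign_strains("single_red", "co_A", 95, 2, 1)$occupant, "fix_plus")
  expect_equal(assign_strains("single_red", "co_B", 95, 2, 1)$occupant, "fix_minus")
  expect_equal(assign_strains("single_green", "co_B", 2, 95, 1)$occupant, "fix_plus")
  # proportional partial-area split for mixed nodules
  mx <- assign_strains("mixed_color", "co_A", 60, 40, 1.0)
  expect_equal(mx$occupant, "mixed")
  expect_equal(mx$partial_area_fix_plus, 0.6)
  expect_equal(mx$partial_area_fix_minus, 0.4)
  # 1-strain plants: both colors, even mixed-color, resolve to that strain
  expect_equal(assign_strains("mixed_color", "fix_minus", 50, 50, 1)$occupant,
               "fix_minus")
  # uninoculated plants: contamination warning, unknown occupant
  expect_warning(out <- assign_strains("single_red", "none", 95, 2, 1),
                 "contamination")
  expect_equal(out$occupant, "unknown")
  expect_equal(assign_strains("nonfluorescent", "co_A", 0, 0, 1)$occupant,
               "unknown")
})

test_that("noise-free well-separated nodules are recovered exactly", {
  cfg <- tiny_cfg(background_noise_sd = 0, p_touching = 0, p_nonfluorescent = 0)
  d <- build_design(1, "domesticated", "co_A", "none")
  set.seed(99)
  truth <- sample_nodule_population(d, cfg, counts = 10L)
  st <- render_mosaic(truth, cfg)
  det <- detect_pipeline(st, d, detection_config())
  expect_equal(nrow(det$nodules), 10)
  # per-nodule area error <= 5% after nearest-centroid matching
  m <- nodulr:::match_nodules(truth |>
                                dplyr::mutate(true_total_area = true_total_area),
                              det$nodules, match_slack = 10)
  expect_equal(nrow(m), 10)
  expect_true(all(abs(m$detected_area - m$true_area) / m$true_area <= 0.05))
  # ledger conservation
  l <- det$ledger
  expect_equal(l$n_initial_features,
               l$n_holes_removed + l$n_below_min + l$n_above_max + l$n_retained)
})

test_that("touching nodules of different colors merge into one mixed-color feature", {
  cfg <- tiny_cfg(background_noise_sd = 0)
  a <- manual_nodule(cfg, "single_fix_plus", color = "red", area = 0.1,
                     cx = 100, cy = 128)
  r <- a$radius_px
  b <- manual_nodule(cfg, "single_fix_minus", color = "green", area = 0.1,
                     cx = 100 + 2 * r - 1, cy = 128, id = "n002")
  st <- render_mosaic(dplyr::bind_rows(a, b), cfg, seed = 12)
  det <- detect_pipeline(st, build_design(1, "wild", "co_A", "none"),
                         detection_config())
  expect_equal(nrow(det$nodules), 1)
  expect_equal(det$nodules$nodule_class, "mixed_color")
  expect_equal(det$nodules$occupant, "mixed")
})

test_that("blank images yield an empty record and a zero ledger", {
  cfg <- tiny_cfg(background_noise_sd = 0)
  st <- render_mosaic(sample_nodule_population(
    build_design(1, "wild", "none", "none"), cfg), cfg, seed = 1)
  det <- detect_pipeline(st, build_design(1, "wild", "none", "none"),
                         detection_config())
  expect_equal(nrow(det$nodules), 0)
  expect_true(all(unlist(det$ledger) == 0))
})
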