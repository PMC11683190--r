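co_design <- function(n_plants, aphid = "none") {
  build_design(n_plants / 2, c("domesticated"), c("co_A", "co_B"), aphid)
}

test_that("identical seed and config reproduce identical nodule tables", {
  cfg <- tiny_cfg()
  d <- build_design(1, c("wild", "domesticated"), c("co_A", "fix_plus"), "none")
  n1 <- sample_nodule_population(d, cfg, place = FALSE, seed = 7)
  n2 <- sample_nodule_population(d, cfg, place = FALSE, seed = 7)
  expect_identical(n1, n2)
  n3 <- sample_nodule_population(d, cfg, place = FALSE, seed = 8)
  expect_false(identical(n1, n3))
})

test_that("partial areas conserve totals and respect occupancy kinds", {
  cfg <- tiny_cfg()
  nod <- sample_nodule_population(co_design(8), cfg, seed = 11,
                                  counts = rep(40L, 8), place = FALSE)
  mixed <- nod[nod$occupancy_kind == "mixed", ]
  expect_gt(nrow(mixed), 10)
  expect_equal(mixed$true_partial_area_fix_plus + mixed$true_partial_area_fix_minus,
               mixed$true_total_area, tolerance = 1e-12)
  singles <- nod[grepl("^single", nod$occupancy_kind), ]
  expect_true(all((singles$true_partial_area_fix_plus > 0) !=
                    (singles$true_partial_area_fix_minus > 0)))
  nonf <- nod[nod$occupancy_kind == "nonfluorescent", ]
  expect_true(all(nonf$true_partial_area_fix_plus == 0 &
                    nonf$true_partial_area_fix_minus == 0))
})

test_that("mixed nodules require both strains and vanish when p_mixed = 0", {
  cfg0 <- tiny_cfg(p_mixed = 0)
  nod <- sample_nodule_population(co_design(4), cfg0, seed = 3,
                                  counts = rep(50L, 4), place = FALSE)
  expect_equal(sum(nod$occupancy_kind == "mixed"), 0)
  # 1-strain plants never host mixed-infection nodules
  d1 <- build_design(2, "wild", c("fix_plus", "fix_minus"), "none")
  nod1 <- sample_nodule_population(d1, tiny_cfg(), seed = 3, counts = rep(50L, 4),
                                   place = FALSE)
  expect_equal(sum(nod1$occupancy_kind == "mixed"), 0)
})

test_that("non-nodulating and uninoculated plants receive no nodules", {
  d <- build_design(1, c("non_nodulating", "wild"), c("none", "fix_plus"), "none")
  nod <- sample_nodule_population(d, tiny_cfg(), seed = 5)
  expect_true(all(nod$plant_id == "B1_wild_fix_plus_none"))
})

test_that("single-nodule area ratios track the configured multipliers", {
  cfg <- effect_config()
  # pooled over co-inoculated plants: Fix+/Fix- mean-area ratio ~ ratio_2strain
  nod <- sample_nodule_population(co_design(16), cfg, seed = 21,
                                  counts = rep(250L, 16), place = FALSE)
  fp <- nod$true_total_area[nod$occupancy_kind == "single_fix_plus"]
  fm <- nod$true_total_area[nod$occupancy_kind == "single_fix_minus"]
  expect_gt(length(fp), 1000)
  expect_equal(mean(fp) / mean(fm), cfg$ratio_2strain, tolerance = 0.08)
  # empirical mixed fraction tracks p_mixed
  expect_equal(mean(nod$occupancy_kind == "mixed"), cfg$p_mixed, tolerance = 0.15)
  # within-nodule split: Fix+/Fix- partial-area ratio ~ within_ratio_no_aphid
  mx <- nod[nod$occupancy_kind == "mixed", ]
  expect_equal(mean(mx$true_partial_area_fix_plus) / mean(mx$true_partial_area_fix_minus),
               cfg$within_ratio_no_aphid, tolerance = 0.08)
})

test_that("swapping co_A and co_B leaves strain-level area distributions unchanged", {
  cfg <- effect_config()
  dA <- build_design(8, "domesticated", "co_A", "none")
  dB <- build_design(8, "domesticated", "co_B", "none")
  nA <- sample_nodule_population(dA, cfg, seed = 31, counts = rep(150L, 8),
                                 place = FALSE)
  nB <- sample_nodule_population(dB, cfg, seed = 32, counts = rep(150L, 8),
                                 place = FALSE)
  mfp <- function(x) mean(x$true_total_area[x$occupancy_kind == "single_fix_plus"])
  mfm <- function(x) mean(x$true_total_area[x$occupancy_kind == "single_fix_minus"])
  expect_equal(mfp(nA), mfp(nB), tolerance = 0.1)
  expect_equal(mfm(nA), mfm(nB), tolerance = 0.1)
  # the color<->strain map is swapped
  expect_equal(unique(nA$color_red_strain), "fix_plus")
  expect_equal(unique(nB$color_red_strain), "fix_minus")
})

test_that("aphid exposure erases the within-nodule split in the default config", {
  cfg <- effect_config()
  no_aphid <- sample_nodule_population(co_design(8, "none"), cfg, seed = 41,
                                       counts = rep(100L, 8), place = FALSE)
  aphid <- sample_nodule_population(co_design(8, "pemv_minus"), cfg, seed = 41,
                                    counts = rep(100L, 8), place = FALSE)
  ratio <- function(x) {
    mx <- x[x$occupancy_kind == "mixed", ]
    mean(mx$true_partial_area_fix_plus) / mean(mx$true_partial_area_fix_minus)
  }
  expect_gt(ratio(no_aphid), 1.2)
  expect_equal(ratio(aphid), 1, tolerance = 0.12)
})

test_that("logCFU draws respect the linear model and the calibrated correlation", {
  areas <- stats::rlnorm(500, log(0.2), 0.45)
  # noiseless line: perfect correlation
  r1 <- stats::cor(areas, sample_cfu(areas, effect_config(cfu_noise_sd = 0), seed = 1))
  expect_equal(r1, 1, tolerance = 1e-12)
  # zero slope: no correlation at large n
  r0 <- stats::cor(areas, sample_cfu(areas, effect_config(cfu_slope = 0, cfu_noise_sd = 1),
                                     seed = 2))
  expect_lt(abs(r0), 0.15)
  # calibrated to the target correlation
  rt <- stats::cor(areas, sample_cfu(areas, effect_config(), seed = 3))
  expect_lt(abs(rt - 0.37), 0.10)
  expect_error(sample_cfu(c(1, -1), effect_config()), "positive")
})

test_that("plant traits reflect inoculum benefits except on non-nodulating plants", {
  cfg <- effect_config()
  d <- build_design(100, "non_nodulating", c("fix_plus", "fix_minus"), "none")
  tr <- sample_plant_traits(d, cfg, seed = 51)
  m <- tapply(tr$shoot_mass, d$inoculum, mean)
  expect_equal(unname(m["fix_plus"]), unname(m["fix_minus"]), tolerance = 0.1)
  d2 <- build_design(100, "domesticated", c("fix_plus", "fix_minus"), "none")
  tr2 <- sample_plant_traits(d2, cfg, seed = 52)
  m2 <- tapply(tr2$shoot_mass, d2$inoculum, mean)
  expect_gt(m2[["fix_plus"]], m2[["fix_minus"]] + 1)
  # titer only defined under PEMV+ aphids
  expect_true(all(is.na(tr2$pemv_titer)))
})

test_that("virus titer rises with within-nodule strictness at the configured slope", {
  cfg <- effect_config(titer_noise_sd = 0.1)
  d <- build_design(50, "domesticated", c("co_A", "co_B"), "pemv_plus")
  strict <- stats::rnorm(nrow(d), 0.33, 0.3)
  tr <- sample_plant_traits(d, cfg, strictness_within = strict, seed = 61)
  fit <- stats::coef(stats::lm(tr$pemv_titer ~ strict))
  expect_equal(unname(fit[2]), cfg$titer_strictness_slope, tolerance = 0.15)
  # strictness is only accepted for co-inoculated PEMV+ plants
  d_bad <- build_design(1, "wild", "fix_plus", "pemv_plus")
  expect_error(sample_plant_traits(d_bad, cfg, strictness_within = 0.5),
               "co-inoculated")
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(effect_config(p_mixed = 1.2), "\\[0, 1\\]")
  expect_error(effect_config(base_nodule_area = -1), "positive")
  expect_error(effect_config(nonsense_field = 1), "unknown")
  expect_error(effect_config(p_mixed = 0.7, p_nonfluorescent = 0.5), "exceed")
})
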