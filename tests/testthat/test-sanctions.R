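simple_nodules <- function(fp_areas, fm_areas, mixed = NULL, plant = "p1") {
  singles <- tibble::tibble(
    nodule_id = paste0("s", seq_len(length(fp_areas) + length(fm_areas))),
    plant_id = plant,
    cx = 0, cy = 0,
    area = c(fp_areas, fm_areas),
    pct_red = NA_real_, pct_green = NA_real_,
    nodule_class = "single_red",
    occupant = rep(c("fix_plus", "fix_minus"), c(length(fp_areas), length(fm_areas))),
    partial_area_fix_plus = c(fp_areas, rep(0, length(fm_areas))),
    partial_area_fix_minus = c(rep(0, length(fp_areas)), fm_areas)
  )
  if (!is.null(mixed)) {
    singles <- dplyr::bind_rows(singles, tibble::tibble(
      nodule_id = paste0("m", seq_len(nrow(mixed))), plant_id = plant,
      cx = 0, cy = 0, area = mixed$fp + mixed$fm,
      pct_red = NA_real_, pct_green = NA_real_,
      nodule_class = "mixed_color", occupant = "mixed",
      partial_area_fix_plus = mixed$fp, partial_area_fix_minus = mixed$fm
    ))
  }
  singles
}

test_that("strictness is the log ratio of mean nodule areas", {
  s <- summarize_sanctions(simple_nodules(2.03, 1.00))
  expect_equal(s$strictness_among, log(2.03))  # ~0.708
  expect_equal(s$n_single_fix_plus, 1L)
  # equal Z values give zero strictness in both modes
  s0 <- summarize_sanctions(simple_nodules(c(1, 2), c(2, 1),
                                           mixed = data.frame(fp = 0.5, fm = 0.5)))
  expect_equal(s0$strictness_among, 0)
  expect_equal(s0$strictness_within, 0)
})

test_that("missing occupant classes leave strictness undefined, never a sentinel", {
  s <- summarize_sanctions(simple_nodules(c(1.2, 0.9), numeric(0)))
  expect_true(is.na(s$strictness_among))
  expect_true(is.na(s$strictness_within))  # no mixed nodules at all
  expect_equal(s$n_single_fix_minus, 0L)
  expect_equal(is_sanctioning(s$strictness_among), factor("undefined", c("yes", "no", "undefined")))
})

test_that("the binary sanctioning call matches the sign of strictness", {
  expect_equal(as.character(is_sanctioning(c(0.71, 0, -0.3, NA))),
               c("yes", "no", "no", "undefined"))
  # consistency with the underlying Z comparison
  set.seed(14)
  for (i in 1:20) {
    zp <- stats::rlnorm(1); zm <- stats::rlnorm(1)
    call <- is_sanctioning(strictness(zp, zm))
    expect_equal(call == "yes", zp > zm)
  }
})

test_that("strictness is antisymmetric and scale-invariant", {
  set.seed(15)
  for (i in 1:20) {
    fp <- stats::rlnorm(5, 0, 0.5); fm <- stats::rlnorm(4, 0, 0.5)
    mixed <- data.frame(fp = stats::rlnorm(3, -1, 0.3), fm = stats::rlnorm(3, -1, 0.3))
    s <- summarize_sanctions(simple_nodules(fp, fm, mixed))
    # swapping Fix+ and Fix- labels negates strictness exactly
    swapped <- summarize_sanctions(simple_nodules(fm, fp,
                                                  data.frame(fp = mixed$fm, fm = mixed$fp)))
    expect_equal(swapped$strictness_among, -s$strictness_among)
    expect_equal(swapped$strictness_within, -s$strictness_within)
    # multiplying every area by a constant changes nothing
    k <- stats::runif(1, 0.1, 10)
    scaled <- summarize_sanctions(simple_nodules(k * fp, k * fm,
                                                 data.frame(fp = k * mixed$fp, fm = k * mixed$fm)))
    expect_equal(scaled$strictness_among, s$strictness_among)
    expect_equal(scaled$strictness_within, s$strictness_within)
  }
})

test_that("generator-level strictness matches the configured sanctions structure", {
  cfg <- effect_config()
  d <- build_design(10, "domesticated", c("co_A", "co_B"), "none")
  nod <- sample_nodule_population(d, cfg, seed = 16, counts = rep(60L, nrow(d)),
                                  place = FALSE)
  s <- summarize_sanctions(truth_as_detected(nod))
  # among-nodule strictness centers near log(ratio_2strain)
  expect_equal(mean(s$strictness_among, na.rm = TRUE), log(cfg$ratio_2strain),
               tolerance = 0.15)
  # within-nodule strictness positive without aphids
  expect_gt(mean(s$strictness_within, na.rm = TRUE), 0)
  # ... and near zero under aphids (within_ratio_aphid = 1)
  da <- build_design(10, "domesticated", c("co_A", "co_B"), "pemv_minus")
  noda <- sample_nodule_population(da, cfg, seed = 17, counts = rep(60L, nrow(da)),
                                   place = FALSE)
  sa <- summarize_sanctions(truth_as_detected(noda))
  expect_lt(abs(mean(sa$strictness_within, na.rm = TRUE)), 0.08)
})

test_that("marker diagnostics read balance from 1-strain plants", {
  cfg <- effect_config()
  d <- build_design(6, "domesticated", c("fix_plus", "fix_minus", "co_A", "co_B"),
                    "none")
  nod <- sample_nodule_population(d, cfg, seed = 18, counts = rep(80L, nrow(d)),
                                  place = FALSE)
  det <- truth_as_detected(nod)
  det$area <- nod$true_total_area
  mb <- marker_balance(det, d)
  expect_true(mb$available)
  # symmetric generator: red/green ratios near 1
  expect_equal(mb$size_ratio_red_green, 1, tolerance = 0.1)
  expect_equal(mb$count_ratio_red_green, 1, tolerance = 0.15)
  # covariate labels follow the labeling scheme
  expect_equal(mb$covariates$fix_plus_marker[mb$covariates$plant_id ==
                                               "B1_domesticated_co_A_none"], "red")
  expect_equal(mb$covariates$fix_plus_marker[mb$covariates$plant_id ==
                                               "B1_domesticated_co_B_none"], "green")
  # attenuated green detection shows up as an imbalanced ratio
  det2 <- det
  green_rows <- det2$nodule_class == "single_green"
  det2$area[green_rows] <- det2$area[green_rows] * 0.5
  mb2 <- marker_balance(det2, d)
  expect_gt(mb2$size_ratio_red_green, 1.5)
  # no 1-strain plants: report flagged unavailable
  dco <- d[d$inoculum %in% c("co_A", "co_B"), ]
  mb3 <- marker_balance(det[det$plant_id %in% dco$plant_id, ], dco)
  expect_false(mb3$available)
})

test_that("plants with too few nodules per class are excluded from regressions", {
  nod <- dplyr::bind_rows(
    simple_nodules(1.5, 1.0, plant = "p1"),
    simple_nodules(numeric(0), 1.0, plant = "p2")
  )
  s <- summarize_sanctions(nod)
  expect_equal(sum(!is.na(s$strictness_among)), 1L)
})
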