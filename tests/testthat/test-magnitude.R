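test_that("magnitude beliefs validate mass and expose conditional moments", {
  bel <- magnitude_belief(c(1, 2), c(0.3, 0.2))
  expect_equal(bel$p_blow, 0.5)
  expect_equal(bel$mean_b, (1 * 0.3 + 2 * 0.2) / 0.5)
  expect_error(magnitude_belief(c(1, 2), c(0.8, 0.4)), "exceeds 1")
  expect_error(magnitude_belief(-1, 0.5), "non-negative")
  expect_true(is.na(magnitude_belief(1, 0)$mean_b))
})

test_that("blow costs must vanish when no blow occurs", {
  expect_error(bivariate_blow_cost(function(r, b) b + 0.1), "vanish")
  expect_s3_class(saturating_protection_cost(), "bivariate_blow_cost")
  expect_error(saturating_protection_cost(g_max = 1.5), "g_max")
})

test_that("full expected blow cost integrates the belief", {
  cb <- bivariate_blow_cost(function(r, b) b * (1 - r))
  bel2 <- magnitude_belief(c(1, 2), c(0.3, 0.2))
  expect_equal(expected_blow_cost_full(cb, bel2, 0.5), 0.35)
  # point mass recovers the discrete model with C_B(r) = c_b(r, b0)
  pm <- point_mass_belief(1.7, 0.4)
  r <- seq(0, 1, 0.1)
  expect_equal(expected_blow_cost_full(cb, pm, r), 0.4 * 1.7 * (1 - r))
  # zero mass costs nothing
  expect_equal(expected_blow_cost_full(cb, magnitude_belief(1, 0), r),
               rep(0, length(r)))
})

test_that("expectation coding matches the full computation exactly for costs
           linear in blow magnitude, and for point masses", {
  cb <- bivariate_blow_cost(function(r, b) b * (1.5 - r))
  set.seed(61)
  r <- seq(0, 1, length.out = 33)
  for (i in 1:30) {
    bel <- random_magnitude_belief()
    expect_equal(expected_blow_cost_expectation_coded(cb, bel, r),
                 expected_blow_cost_full(cb, bel, r), tolerance = 1e-12)
  }
  cb_nl <- bivariate_blow_cost(function(r, b) sqrt(b) * (1 - 0.5 * r))
  pm <- point_mass_belief(2.3, 0.6)
  expect_equal(expected_blow_cost_expectation_coded(cb_nl, pm, r),
               expected_blow_cost_full(cb_nl, pm, r), tolerance = 1e-12)
})

test_that("for costs concave in magnitude, expectation coding overstates the
           expected blow cost (Jensen)", {
  cb <- bivariate_blow_cost(function(r, b) sqrt(b) * (1 - 0.5 * r))
  bel <- magnitude_belief(c(1, 4), c(0.25, 0.25))
  r <- c(0, 0.4, 0.9)
  expect_true(all(expected_blow_cost_expectation_coded(cb, bel, r) >
                    expected_blow_cost_full(cb, bel, r)))
})

test_that("zero blow mass yields zero expectation-coded cost with a message", {
  cb <- bivariate_blow_cost(function(r, b) b * (1 - r))
  expect_message(
    v <- expected_blow_cost_expectation_coded(cb, magnitude_belief(1, 0), 0.5),
    "zero blow mass")
  expect_identical(v, 0)
})

test_that("with a point-mass belief the magnitude model reproduces the
           discrete model verbatim", {
  set.seed(71)
  for (i in 1:20) {
    fam <- random_cost_family()
    cb <- embed_family_as_bivariate(fam)
    p <- stats::runif(1)
    pm <- point_mass_belief(1, p)
    r0_disc <- optimal_startle(fam, p, check_assumptions = FALSE)$r0
    for (coding in c("full", "expectation")) {
      opt <- optimal_startle_magnitude_model(cb, pm, fam, coding = coding)
      expect_equal(opt$r0, r0_disc, tolerance = 1e-6)
      expect_lt(abs(opt$r0 - oracle_r0_family(fam, p)), 1e-4 + 1e-9)
    }
    # blow-probability monotonicity carries over
    ps <- sort(stats::runif(2))
    r0s <- vapply(ps, function(pp)
      optimal_startle_magnitude_model(cb, point_mass_belief(1, pp), fam,
                                      coding = "full")$r0, 0)
    expect_gte(r0s[2], r0s[1] - 1e-6)
  }
})

test_that("raising the blow mass raises the optimum under both codings when
           startle stays effective", {
  fam <- make_cost_family()
  cb <- bivariate_blow_cost(function(r, b) b * (1 - 0.8 * r))
  for (coding in c("full", "expectation")) {
    r0s <- vapply(c(0.2, 0.5, 0.9), function(p)
      optimal_startle_magnitude_model(cb, point_mass_belief(1.5, p), fam,
                                      coding = coding)$r0, 0)
    expect_true(all(diff(r0s) > 0))
  }
})

test_that("an expected magnitude beyond the effectiveness cutoff collapses the
           expectation-coded optimum", {
  fam <- make_cost_family()
  cb <- saturating_protection_cost(b_crit = 2)
  below <- optimal_startle_magnitude_model(cb, point_mass_belief(1.9, 0.6),
                                           fam, coding = "expectation")
  above <- optimal_startle_magnitude_model(cb, point_mass_belief(2.1, 0.6),
                                           fam, coding = "expectation")
  expect_gt(below$r0, 0.1)
  expect_lt(above$r0, below$r0)
  expect_identical(above$r0, 0)
})

test_that("expectation coding can never beat full coding on the true objective", {
  fam <- make_cost_family()
  cb <- saturating_protection_cost()
  set.seed(81)
  for (i in 1:20) {
    bel <- random_magnitude_belief()
    full <- optimal_startle_magnitude_model(cb, bel, fam, coding = "full")
    exp_opt <- optimal_startle_magnitude_model(cb, bel, fam, coding = "expectation")
    true_cost_at_exp <- startle_side_cost(fam, exp_opt$r0) +
      expected_blow_cost_full(cb, bel, exp_opt$r0)
    expect_lte(full$c0, true_cost_at_exp + 1e-9)
  }
})

test_that("effectiveness violations are located on the magnitude axis", {
  ok <- bivariate_blow_cost(function(r, b) b * (1 - r))
  expect_identical(nrow(effectiveness_violation_ranges(ok, b_domain = c(0.1, 4))),
                   0L)
  vr <- effectiveness_violation_ranges(saturating_protection_cost(b_crit = 2),
                                       b_domain = c(0.1, 4), n_grid = 201)
  expect_identical(nrow(vr), 1L)
  expect_equal(vr$b_lo, 2, tolerance = 0.05)
  expect_equal(vr$b_hi, 4)

  expect_message(
    empty <- effectiveness_violation_ranges(ok, r_domain = c(0.5, 0.5),
                                            b_domain = c(0.1, 4)),
    "zero width")
  expect_identical(nrow(empty), 0L)
  expect_error(effectiveness_violation_ranges(ok, b_domain = c(0, 4)),
               "positive lower end")
})
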