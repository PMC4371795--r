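test_that("total cost reduces to startle cost when no blow is expected", {
  fam <- make_cost_family()
  r <- seq(0, 1, length.out = 21)
  expect_equal(total_cost(fam, 0, r),
               fam$fns$c_r_direct(r) + fam$fns$c_r_forgone(r))
})

test_that("total cost matches direct arithmetic on a closed-form family", {
  fam <- reduced_quadratic_family()
  expect_equal(total_cost(fam, 0.5, 0.5), 0.5)          # 0.25 + 0.5 * 0.5
  expect_equal(total_cost(fam, blow_belief(0.5), 0.5), 0.5)
})

test_that("total cost is affine in blow probability and in eta at fixed r", {
  fam <- make_cost_family()
  r <- 0.37
  p_grid <- seq(0, 1, 0.25)
  vals_p <- vapply(p_grid, function(p) total_cost(fam, p, r), 0)
  expect_equal(diff(vals_p, differences = 2), rep(0, 3), tolerance = 1e-12)

  etas <- c(0, 0.5, 1, 1.5, 2)
  vals_eta <- vapply(etas, function(e)
    total_cost(scale_opportunity(fam, e), 0.4, r), 0)
  expect_equal(diff(vals_eta, differences = 2), rep(0, 3), tolerance = 1e-12)
})

test_that("total cost rejects out-of-domain r and names non-finite components", {
  fam <- make_cost_family()
  expect_error(total_cost(fam, 0.5, 1.2), "outside domain")
  expect_error(total_cost(fam, 0.5, -0.1), "outside domain")
  expect_error(total_cost(fam, 1.5, 0.5), "probability")

  # non-finite only on a sliver the construction probe grid cannot hit
  bad <- make_cost_family("custom",
    params = list(c_r_direct = function(r)
      ifelse(abs(r - 0.5000001) < 1e-6, NaN, r)))
  expect_error(total_cost(bad, 0.5, 0.5000001), "c_r_direct")
})

test_that("solver recovers the closed-form minimiser r0 = p/2", {
  fam <- reduced_quadratic_family()
  for (p in c(0, 0.2, 0.5, 0.6, 0.9, 1)) {
    opt <- optimal_startle(fam, p, check_assumptions = FALSE)
    expect_equal(opt$r0, p / 2, tolerance = 1e-6)
    expect_equal(opt$c0, total_cost(fam, p, opt$r0), tolerance = 1e-10)
  }
})

test_that("with only increasing startle cost the optimum sits at the floor", {
  fam <- make_cost_family("custom",
                          params = list(c_r_direct = function(r) r^2 + 0.1 * r))
  opt <- optimal_startle(fam, 0, check_assumptions = FALSE)
  expect_identical(opt$r0, 0)
})

test_that("ties on a flat cost resolve to the smallest startle magnitude", {
  flat <- make_cost_family("custom",
                           params = list(c_r_direct = function(r) rep(1, length(r))))
  expect_identical(optimal_startle(flat, 0.5, check_assumptions = FALSE)$r0, 0)
})

test_that("solver requires a passing audit unless explicitly waived", {
  fam <- reduced_quadratic_family()   # no opportunity costs: audit must fail
  expect_error(optimal_startle(fam, 0.5), "waive")
  expect_silent(optimal_startle(fam, 0.5, check_assumptions = FALSE))
})

test_that("solver agrees with the exhaustive grid-search oracle on shipped forms", {
  set.seed(21)
  fams <- list(make_cost_family(), make_cost_family("linear"),
               make_cost_family("logistic"), random_cost_family(),
               random_cost_family("linear"))
  step <- 1 / (1e4 - 1)
  for (fam in fams) {
    for (p in stats::runif(3)) {
      r0 <- optimal_startle(fam, p, check_assumptions = FALSE)$r0
      expect_lt(abs(r0 - oracle_r0_family(fam, p)), step + 1e-9)
    }
  }
})

test_that("raising the blow probability never lowers the optimal startle", {
  set.seed(31)
  for (i in 1:40) {
    fam <- random_cost_family()
    ps <- sort(stats::runif(2))
    r0_lo <- optimal_startle(fam, ps[1], check_assumptions = FALSE)$r0
    r0_hi <- optimal_startle(fam, ps[2], check_assumptions = FALSE)$r0
    expect_gte(r0_hi, r0_lo - 1e-6)
  }
})

test_that("raising the opportunity scale never lowers the optimal startle
           within the applicability range of the slope assumption", {
  set.seed(41)
  for (i in 1:40) {
    fam <- random_cost_family()
    pf <- applicable_p_floor(fam)
    p <- stats::runif(1, min(pf * 1.05 + 0.01, 0.99), 1)
    etas <- sort(stats::runif(2, 1, 4))
    r0_lo <- optimal_startle(scale_opportunity(fam, etas[1]), p,
                             check_assumptions = FALSE)$r0
    r0_hi <- optimal_startle(scale_opportunity(fam, etas[2]), p,
                             check_assumptions = FALSE)$r0
    expect_gte(r0_hi, r0_lo - 1e-6)
  }
})
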