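test_that("probe posterior follows the forward-model arithmetic", {
  expect_equal(posterior_with_probe(forward_model(1, 0.5, 0.3))$p_blow, 0.6)
  expect_equal(posterior_with_probe(forward_model(1, 0.5, 0))$p_blow, 0)
  expect_equal(posterior_context_only(forward_model(1, 0.5, p_b_prior = 0.1))$p_blow,
               0.2)
  expect_equal(posterior_context_only(forward_model(1, 0.5, p_b_prior = 0))$p_blow,
               0)
})

test_that("CS-alone posterior is exactly zero for a fully heralded blow and
           follows the arithmetic otherwise", {
  fm <- forward_model(p_s = 0.5, p_b_given_cs = 0.5)
  expect_identical(posterior_without_probe(fm, 0)$p_blow, 0)
  expect_equal(posterior_without_probe(fm, 0.01)$p_blow, 0.01)
  expect_equal(posterior_without_probe(forward_model(p_s = 0.5, p_b_given_cs = 0),
                                       0.5)$p_blow, 0)
})

test_that("posteriors are monotone in the association and prior arguments", {
  assoc <- seq(0, 0.9, 0.1)
  probe <- vapply(assoc, function(a)
    posterior_with_probe(forward_model(1, 0.96, a))$p_blow, 0)
  expect_true(all(diff(probe) > 0))
  priors <- seq(0, 0.9, 0.1)
  ctx <- vapply(priors, function(q)
    posterior_context_only(forward_model(1, 0.96, p_b_prior = q))$p_blow, 0)
  expect_true(all(diff(ctx) > 0))
})

test_that("invalid forward-model regimes raise domain errors", {
  expect_error(forward_model(p_s = 0), "positive")
  expect_error(forward_model(p_s_given_b = 1.2), "probability")
  expect_error(posterior_without_probe(forward_model(p_s = 1, p_b_given_cs = 0.5),
                                       0.1), "positive")
  expect_warning(posterior_with_probe(forward_model(1, 0.1, 0.9)), "clamped")
})

test_that("a stronger CS association yields a stronger optimal startle
           (fear-potentiated startle, end to end)", {
  set.seed(51)
  for (i in 1:10) {
    fam <- random_cost_family()
    fm_minus <- forward_model(1, 0.96, p_b_given_cs = 0.05)
    fm_plus <- forward_model(1, 0.96, p_b_given_cs = stats::runif(1, 0.2, 0.9))
    p_minus <- posterior_with_probe(fm_minus)$p_blow
    p_plus <- posterior_with_probe(fm_plus)$p_blow
    expect_gt(p_plus, p_minus)
    r0_minus <- optimal_startle(fam, p_minus, check_assumptions = FALSE)$r0
    r0_plus <- optimal_startle(fam, p_plus, check_assumptions = FALSE)$r0
    expect_gte(r0_plus, r0_minus - 1e-6)
  }
})

test_that("shipped scenario parameter sets never trigger the posterior clamp", {
  expect_no_warning(run_all_scenarios())
})
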