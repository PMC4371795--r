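trial_rec <- function(cs = "CS+", us = TRUE, mag = 1) {
  list(cs = cs, us_present = us, us_magnitude = if (us) mag else 0)
}

test_that("Rescorla-Wagner updates follow the delta rule", {
  st <- init_learner("rescorla-wagner", list(alpha = 0.5))
  st <- update_association(st, trial_rec())
  expect_equal(association_estimate(st, "CS+"), 0.5)
  st <- update_association(st, trial_rec())
  expect_equal(association_estimate(st, "CS+"), 0.75)
  # omission with V = 0 is a fixed point
  st0 <- init_learner("rescorla-wagner", list(alpha = 0.5))
  st0 <- update_association(st0, trial_rec(us = FALSE))
  expect_equal(association_estimate(st0, "CS+"), 0)
  # magnitude trace follows the same recursion on observed magnitudes:
  # 0.5, 0.75 after two b = 1 trials, then 0.75 + 0.5 (2 - 0.75)
  st <- update_association(st, trial_rec(mag = 2))
  expect_equal(magnitude_sparse_estimate(st, "CS+"), 1.375)
})

test_that("beta-bernoulli updates give the conjugate posterior mean", {
  st <- init_learner("beta-bernoulli")
  for (i in 1:3) st <- update_association(st, trial_rec())
  expect_equal(association_estimate(st, "CS+"), 4 / 5)
  expect_equal(magnitude_sparse_estimate(st, "CS+"), 3 / 4)  # prior weight 1 at 0
})

test_that("with a stationary reinforcement schedule the association converges
           to the empirical rate", {
  set.seed(91)
  us <- stats::rbinom(1000, 1, 0.3)
  st <- init_learner("beta-bernoulli")
  for (u in us) st <- update_association(st, trial_rec(us = u == 1))
  expect_equal(association_estimate(st, "CS+"), mean(us), tolerance = 0.05)
})

test_that("protocols validate their trial structure and learning rule", {
  expect_error(conditioning_protocol(0, 0, 1), "at least one trial")
  expect_error(conditioning_protocol(5, 5, 1, rule = "nope"), "unknown learning rule")
  expect_error(conditioning_protocol(5, 5, 1, rule = "rescorla-wagner",
                                     rule_params = list(alpha = 2)), "alpha")
  tr <- data.frame(cs = "CS+", us_present = FALSE, us_magnitude = 1,
                   probe_present = TRUE)
  expect_error(protocol(tr), "only when")
  tr2 <- data.frame(cs = "CS?", us_present = FALSE, us_magnitude = 0,
                    probe_present = TRUE)
  expect_error(protocol(tr2), "unknown cs level")
})

test_that("simulated trajectories are deterministic given protocol and seed", {
  prot <- conditioning_protocol(5, 10, 1.2, seed = 3L)
  t1 <- run_protocol(prot)
  t2 <- run_protocol(prot)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "seed"), 3L)
  expect_identical(nrow(t1), 15L)
  expect_true(all(t1$p_post >= 0 & t1$p_post <= 1))
})

test_that("a never-reinforced CS with zero initial association yields a flat
           near-zero startle trajectory", {
  tr <- data.frame(cs = "CS-", us_present = FALSE, us_magnitude = 0,
                   probe_present = TRUE)[rep(1, 12), ]
  prot <- protocol(tr, rule = "rescorla-wagner", rule_params = list(alpha = 0.3))
  traj <- run_protocol(prot)
  expect_true(all(traj$p_post == 0))
  expect_true(all(traj$r0_full == 0) && all(traj$r0_exp == 0))
  expect_identical(classify_trajectory_shape(traj$r0_exp), "flat")
})

test_that("startle grows during acquisition and declines during extinction
           for a medium-magnitude US", {
  traj <- run_protocol(conditioning_protocol(10, 20, 1.2))
  acq <- traj$r0_exp[traj$phase == "acquisition"]
  ext <- traj$r0_exp[traj$phase == "extinction"]
  expect_true(all(diff(acq) > -1e-9))
  expect_gt(max(acq), 0.2)
  expect_identical(classify_trajectory_shape(ext), "monotone-decreasing")
  expect_identical(classify_trajectory_shape(traj$r0_full[traj$phase == "extinction"]),
                   "monotone-decreasing")
})

test_that("learning alone potentiates the very first probe after acquisition", {
  tr <- data.frame(
    cs = "CS+",
    us_present = rep(c(TRUE, FALSE), c(10, 1)),
    us_magnitude = rep(c(1.2, 0), c(10, 1)),
    probe_present = rep(c(FALSE, TRUE), c(10, 1)),
    phase = rep(c("acquisition", "extinction"), c(10, 1)))
  traj <- run_protocol(protocol(tr))
  # probe-free CS trials elicit (essentially) nothing
  expect_true(all(traj$p_post[1:10] == 0))
  expect_true(all(traj$r0_exp[1:10] == 0))
  # the first-ever probe+CS pairing is already potentiated
  expect_gt(traj$p_post[11], 0.9)
  expect_gt(traj$r0_exp[11], 0.2)
})

test_that("response noise is optional, multiplicative and seed-reproducible", {
  model <- startle_model(noise_sd = 0.2)
  prot <- conditioning_protocol(5, 5, 1.2, seed = 17L)
  t1 <- run_protocol(prot, model)
  t2 <- run_protocol(prot, model)
  expect_identical(t1$r_obs_exp, t2$r_obs_exp)
  expect_false(all(t1$r_obs_exp == t1$r0_exp))
  # noiseless runs do not carry observation columns
  expect_null(run_protocol(prot)$r_obs_exp)
})

test_that("trajectory shapes are classified by collapsed sign patterns", {
  expect_identical(classify_trajectory_shape(c(1, 1, 1)), "flat")
  expect_identical(classify_trajectory_shape(c(3, 2, 2, 1)), "monotone-decreasing")
  expect_identical(classify_trajectory_shape(c(0, 0, 1, 2, 1.5, 0.5)),
                   "rise-then-fall")
  expect_identical(classify_trajectory_shape(c(0, 1, 0.5, 1.5)), "other")
  expect_identical(classify_trajectory_shape(c(1, 2, 3)), "monotone-increasing")
})

test_that("the medium/high US comparison dissociates the two codings", {
  dav <- davis_astrachan_scenario()
  sh <- dav$shapes
  get_shape <- function(g, c) sh$shape[sh$group == g & sh$coding == c]
  expect_identical(get_shape("medium", "expectation"), "monotone-decreasing")
  expect_identical(get_shape("high", "expectation"), "rise-then-fall")
  expect_false(get_shape("high", "full") == "rise-then-fall")
  # full coding never pays more than expectation coding in the true objective
  for (g in c("medium", "high")) {
    traj <- dav[[g]]
    expect_true(all(traj$cost_full <= traj$cost_full_at_exp + 1e-9))
  }
  # conditioning with the very strong US potentiates startle less
  end_acq <- function(traj) tail(traj$r0_exp[traj$phase == "acquisition"], 1)
  expect_lte(end_acq(dav$high), end_acq(dav$medium))
})

test_that("the US comparison refuses configurations outside the violation regime", {
  expect_error(davis_astrachan_scenario(medium_b = 2.5),
               "medium_b")
  expect_error(davis_astrachan_scenario(high_b = 1.5),
               "high_b")
  model_ok <- startle_model(
    blow_cost = bivariate_blow_cost(function(r, b) b * (1 - 0.8 * r)))
  expect_error(davis_astrachan_scenario(model = model_ok),
               "no effectiveness-violation range")
})
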