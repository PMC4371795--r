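#' Build a trial-level conditioning protocol
#'
#' A protocol is an ordered trial list plus a learning rule and an RNG seed.
#' Each trial presents a stimulus (`"CS+"`, `"CS-"` or `"context"`), may
#' deliver an unconditioned stimulus (US, the aversive blow surrogate) of a
#' given magnitude, and may present the startle probe. [conditioning_protocol()]
#' builds the standard acquisition-then-extinction layout: `n_acquisition`
#' reinforced CS+ trials followed by `n_extinction` non-reinforced CS+
#' trials, with the probe on every trial.
#'
#' @param n_acquisition Number of reinforced trials.
#' @param n_extinction Number of non-reinforced trials.
#' @param us_magnitude Magnitude of the US on reinforced trials (`> 0`).
#' @param cs Conditioned stimulus label used throughout.
#' @param rule Learning rule, `"beta-bernoulli"` or `"rescorla-wagner"`.
#' @param rule_params Named list of rule parameters (see
#'   [update_association()]).
#' @param seed Integer RNG seed recorded in all outputs.
#' @return An object of class `startle_protocol`.
#' @seealso [protocol()], [run_protocol()]
#' @export
conditioning_protocol <- function(n_acquisition, n_extinction, us_magnitude,
                                  cs = "CS+", rule = "beta-bernoulli",
                                  rule_params = list(), seed = 1L) {
  stopifnot(n_acquisition >= 0, n_extinction >= 0)
  n <- n_acquisition + n_extinction
  if (n == 0) stop("protocol needs at least one trial")
  trials <- data.frame(
    trial = seq_len(n),
    cs = cs,
    us_present = rep(c(TRUE, FALSE), c(n_acquisition, n_extinction)),
    us_magnitude = rep(c(us_magnitude, 0), c(n_acquisition, n_extinction)),
    probe_present = TRUE,
    phase = rep(c("acquisition", "extinction"), c(n_acquisition, n_extinction)))
  protocol(trials, rule = rule, rule_params = rule_params, seed = seed)
}

#' @rdname conditioning_protocol
#' @param trials Data frame with columns `cs`, `us_present`, `us_magnitude`,
#'   `probe_present` and optionally `trial` and `phase`.
#' @export
protocol <- function(trials, rule = "beta-bernoulli", rule_params = list(),
                     seed = 1L) {
  need <- c("cs", "us_present", "us_magnitude", "probe_present")
  if (!is.data.frame(trials) || !all(need %in% names(trials)))
    stop(sprintf("`trials` must be a data frame with columns %s",
                 paste(need, collapse = ", ")))
  if (!nrow(trials)) stop("protocol needs at least one trial")
  if (is.null(trials$trial)) trials$trial <- seq_len(nrow(trials))
  if (is.null(trials$phase)) trials$phase <- NA_character_
  if (any(trials$us_magnitude < 0))
    stop("`us_magnitude` must be non-negative")
  if (any(trials$us_magnitude > 0 & !trials$us_present))
    stop("`us_magnitude` must be positive only when `us_present` is TRUE")
  if (any(trials$us_present & trials$us_magnitude <= 0))
    stop("US trials must carry a positive `us_magnitude`")
  bad <- setdiff(unique(trials$cs), c("CS+", "CS-", "context"))
  if (length(bad))
    stop(sprintf("unknown cs level(s): %s", paste(bad, collapse = ", ")))
  .validate_rule(rule, rule_params)
  structure(list(trials = trials, rule = rule,
                 rule_params = .rule_defaults(rule, rule_params),
                 seed = as.integer(seed)),
            class = "startle_protocol")
}

#' @export
print.startle_protocol <- function(x, ...) {
  cat(sprintf("<startle_protocol> %d trials, rule = '%s', seed = %d\n",
              nrow(x$trials), x$rule, x$seed))
  invisible(x)
}

.rule_defaults <- function(rule, rule_params) {
  defaults <- switch(rule,
    "beta-bernoulli" = list(a0 = 1, b0 = 1, mag_prior_mean = 0,
                            mag_prior_weight = 1),
    "rescorla-wagner" = list(alpha = 0.2, v0 = 0, b0_sparse = 0))
  utils::modifyList(defaults, rule_params)
}

.validate_rule <- function(rule, rule_params) {
  if (!rule %in% c("beta-bernoulli", "rescorla-wagner"))
    stop(sprintf("unknown learning rule '%s'", rule))
  p <- .rule_defaults(rule, rule_params)
  if (rule == "beta-bernoulli") {
    if (p$a0 <= 0 || p$b0 <= 0)
      stop("beta-bernoulli pseudo-counts must be positive")
    if (p$mag_prior_weight <= 0)
      stop("beta-bernoulli magnitude prior weight must be positive")
  } else {
    if (p$alpha <= 0 || p$alpha > 1)
      stop("rescorla-wagner rate alpha must lie in (0, 1]")
  }
  invisible(TRUE)
}

#' Initialise a learner state
#'
#' Creates the per-stimulus learning state consumed by
#' [update_association()]: the CS–blow association estimate, the sparse
#' scalar blow-magnitude expectation, and the empirical histogram of US
#' magnitudes used by the full-distribution coder.
#'
#' @param rule,rule_params Learning rule and parameters as in [protocol()].
#' @param cs_levels Stimulus labels to track.
#' @return An object of class `learner_state`.
#' @export
init_learner <- function(rule = "beta-bernoulli", rule_params = list(),
                         cs_levels = c("CS+", "CS-", "context")) {
  .validate_rule(rule, rule_params)
  p <- .rule_defaults(rule, rule_params)
  per_cs <- stats::setNames(lapply(cs_levels, function(cs) {
    list(n_trials = 0L, n_us = 0L, sum_obs_mag = 0,
         mag_counts = numeric(0),        # named by magnitude value
         v = if (rule == "rescorla-wagner") p$v0 else NA_real_,
         b_sparse_rw = if (rule == "rescorla-wagner") p$b0_sparse else NA_real_)
  }), cs_levels)
  structure(list(rule = rule, params = p, cs = per_cs),
            class = "learner_state")
}

#' Update the learner from one trial
#'
#' Applies one step of the chosen learning rule to the state for the trial's
#' stimulus:
#'
#' * `"beta-bernoulli"`: conjugate posterior-mean update of the association —
#'   with prior pseudo-counts `(a0, b0)`, the estimate after `n` trials of
#'   which `k` were reinforced is `(a0 + k) / (a0 + b0 + n)`.
#' * `"rescorla-wagner"`: `V <- V + alpha * (lambda - V)` with `lambda = 1`
#'   on US trials and 0 otherwise.
#'
#' The blow-magnitude expectation is updated by the same rule applied to the
#' *observed outcome magnitude* of every trial of that stimulus — the US
#' magnitude on reinforced trials and 0 on omission trials. This single
#' scalar is the sparse "expectation coding" signal: it cannot distinguish a
#' less probable blow from a weaker one, which is exactly the simplification
#' whose behavioural signature the simulator exposes. Separately, the
#' histogram of magnitudes observed on US trials (the conditional
#' distribution, available to a full-distribution coder) is accumulated.
#'
#' @param state A [learner_state][init_learner].
#' @param trial One trial: a list or one-row data frame with `cs`,
#'   `us_present`, `us_magnitude`.
#' @param rule Optional rule name; must match the state's rule if given.
#' @return The updated `learner_state`.
#' @examples
#' st <- init_learner("rescorla-wagner", list(alpha = 0.5))
#' st <- update_association(st, list(cs = "CS+", us_present = TRUE, us_magnitude = 1))
#' association_estimate(st, "CS+")  # 0.5
#' @export
update_association <- function(state, trial, rule = NULL) {
  stopifnot(inherits(state, "learner_state"))
  if (!is.null(rule) && rule != state$rule)
    stop(sprintf("state was initialised with rule '%s', not '%s'",
                 state$rule, rule))
  if (is.data.frame(trial)) trial <- as.list(trial[1, ])
  cs <- trial$cs
  if (is.null(state$cs[[cs]]))
    stop(sprintf("learner does not track stimulus '%s'", cs))
  us <- isTRUE(trial$us_present)
  mag <- if (us) trial$us_magnitude else 0
  s <- state$cs[[cs]]
  s$n_trials <- s$n_trials + 1L
  s$n_us <- s$n_us + as.integer(us)
  s$sum_obs_mag <- s$sum_obs_mag + mag
  if (us) {
    key <- format(trial$us_magnitude, digits = 15)
    s$mag_counts[key] <- (if (is.na(s$mag_counts[key])) 0
                          else s$mag_counts[key]) + 1
  }
  if (state$rule == "rescorla-wagner") {
    a <- state$params$alpha
    s$v <- s$v + a * (as.numeric(us) - s$v)
    s$b_sparse_rw <- s$b_sparse_rw + a * (mag - s$b_sparse_rw)
  }
  state$cs[[cs]] <- s
  state
}

#' Current association estimate \eqn{P(B|CS)} for a stimulus
#'
#' @param state A [learner_state][init_learner].
#' @param cs Stimulus label.
#' @return Probability estimate in `[0, 1]`.
#' @export
association_estimate <- function(state, cs) {
  stopifnot(inherits(state, "learner_state"))
  s <- state$cs[[cs]]
  if (is.null(s)) stop(sprintf("learner does not track stimulus '%s'", cs))
  if (state$rule == "beta-bernoulli") {
    p <- state$params
    (p$a0 + s$n_us) / (p$a0 + p$b0 + s$n_trials)
  } else {
    s$v
  }
}

#' Sparse (expectation-coded) blow-magnitude estimate for a stimulus
#'
#' The single-scalar magnitude expectation tracked by the learner (see
#' [update_association()]). Under `"beta-bernoulli"` it is the
#' prior-weighted mean of all observed outcome magnitudes (zeros included);
#' under `"rescorla-wagner"` the delta-rule trace toward each observed
#' magnitude.
#'
#' @inheritParams association_estimate
#' @return Non-negative scalar.
#' @export
magnitude_sparse_estimate <- function(state, cs) {
  stopifnot(inherits(state, "learner_state"))
  s <- state$cs[[cs]]
  if (is.null(s)) stop(sprintf("learner does not track stimulus '%s'", cs))
  if (state$rule == "beta-bernoulli") {
    p <- state$params
    (p$mag_prior_weight * p$mag_prior_mean + s$sum_obs_mag) /
      (p$mag_prior_weight + s$n_trials)
  } else {
    s$b_sparse_rw
  }
}

#' Full-distribution magnitude belief for a stimulus
#'
#' Builds the [magnitude_belief()] available to a full-distribution coder:
#' the empirical histogram of US magnitudes observed for the stimulus
#' (conditional distribution given a blow), scaled by the blow probability
#' `p_blow`. With no US observed yet the belief carries zero mass.
#'
#' @inheritParams association_estimate
#' @param p_blow Blow-occurrence probability to place on the histogram.
#' @return A [magnitude_belief()].
#' @export
magnitude_full_belief <- function(state, cs, p_blow) {
  stopifnot(inherits(state, "learner_state"))
  s <- state$cs[[cs]]
  if (is.null(s)) stop(sprintf("learner does not track stimulus '%s'", cs))
  if (s$n_us == 0L || p_blow == 0)
    return(magnitude_belief(support = 0, probs = 0))
  magnitude_belief(support = as.numeric(names(s$mag_counts)),
                   probs = p_blow * s$mag_counts / s$n_us)
}

#' Assemble the model configuration for trial-level simulation
#'
#' Bundles the components [run_protocol()] needs: the startle-side cost
#' family, the bivariate blow cost, the forward model supplying
#' \eqn{P(S|B)} and \eqn{P(S)}, and solver settings.
#'
#' @param startle_costs A [cost_family][make_cost_family]; its startle-side
#'   terms (direct and opportunity) enter the objective.
#' @param blow_cost A [bivariate_blow_cost()].
#' @param forward A [forward_model()]; its `p_b_given_cs` slot is replaced
#'   trial by trial with the learner's current association.
#' @param p_nos_given_b \eqn{P(\neg S|B)} used on probe-free trials (default
#'   0: a blow is never unheralded, so CS-alone trials elicit no startle).
#' @param epsilon_startle Posterior threshold below which a startle is
#'   reported as "not elicited" in summaries.
#' @param n_grid,tol Solver settings per trial.
#' @param noise_sd Standard deviation (log scale) of optional multiplicative
#'   response noise; 0 (default) disables it and makes runs fully
#'   deterministic.
#' @param check_assumptions Audit `startle_costs` at construction; waive
#'   explicitly for violation-regime configurations.
#' @return An object of class `startle_model`.
#' @export
startle_model <- function(startle_costs = make_cost_family(),
                          blow_cost = saturating_protection_cost(),
                          forward = forward_model(),
                          p_nos_given_b = 0,
                          epsilon_startle = 1e-3,
                          n_grid = 512L, tol = 1e-8, noise_sd = 0,
                          check_assumptions = TRUE) {
  stopifnot(inherits(startle_costs, "cost_family"),
            inherits(blow_cost, "bivariate_blow_cost"),
            inherits(forward, "forward_model"))
  if (isTRUE(check_assumptions)) {
    rep <- audit_assumptions(startle_costs, n_grid = 41L)
    if (!all(rep$passed))
      stop(paste0("startle cost family violates assumption(s): ",
                  paste(rep$assumption[!rep$passed], collapse = ", "),
                  "; pass check_assumptions = FALSE to waive"))
  }
  structure(list(startle_costs = startle_costs, blow_cost = blow_cost,
                 forward = forward, p_nos_given_b = p_nos_given_b,
                 epsilon_startle = epsilon_startle,
                 n_grid = as.integer(n_grid), tol = tol, noise_sd = noise_sd),
            class = "startle_model")
}

#' Simulate a conditioning protocol trial by trial
#'
#' Runs the learner through the protocol and, on every trial, computes the
#' blow posterior and the cost-minimising startle magnitude under both
#' magnitude codings *before* the trial's outcome updates the learner (the
#' probe precedes the US). On probe trials the posterior is
#' \eqn{P(S|B) P(B|CS)/P(S)} with the learner's current association (the
#' context prior plays that role on `"context"` trials); on probe-free
#' trials it is the near-zero CS-alone posterior
#' \eqn{P(\neg S|B) P(B|CS)/P(\neg S)}.
#'
#' The returned trajectory is a data frame with one row per trial and
#' columns `trial`, `phase`, `cs`, `us`, `b`, `p_assoc`, `mean_b`, `p_post`,
#' `r0_full`, `r0_exp`, `cost_full`, `cost_exp`, `cost_full_at_exp`
#' (the full-distribution objective evaluated at the expectation-coded
#' optimum — the suboptimality witness), plus `r_obs_full` / `r_obs_exp`
#' when response noise is enabled. Runs are deterministic given the protocol
#' seed.
#'
#' @param protocol A [startle_protocol][conditioning_protocol].
#' @param model A [startle_model()].
#' @return A data frame of class `startle_trajectory`; the protocol, model
#'   and seed are attached as attributes.
#' @export
run_protocol <- function(protocol, model = startle_model()) {
  stopifnot(inherits(protocol, "startle_protocol"),
            inherits(model, "startle_model"))
  trials <- protocol$trials
  n <- nrow(trials)
  st <- init_learner(protocol$rule, protocol$rule_params,
                     cs_levels = unique(c(trials$cs, "context")))
  fm <- model$forward
  cols <- c("p_assoc", "mean_b", "p_post", "r0_full", "r0_exp",
            "cost_full", "cost_exp", "cost_full_at_exp")
  rec <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (i in seq_len(n)) {
    tr <- as.list(trials[i, ])
    p_assoc <- association_estimate(st, tr$cs)
    b_sparse <- magnitude_sparse_estimate(st, tr$cs)
    fm_i <- forward_model(fm$p_s_given_b, fm$p_s,
                          p_b_given_cs = p_assoc, p_b_prior = fm$p_b_prior)
    p_post <- if (isTRUE(tr$probe_present)) {
      posterior_with_probe(fm_i)$p_blow
    } else {
      posterior_without_probe(fm_i, model$p_nos_given_b)$p_blow
    }
    bel_full <- magnitude_full_belief(st, tr$cs, p_post)
    bel_exp <- point_mass_belief(b_sparse, p_post)
    opt_full <- optimal_startle_magnitude_model(
      model$blow_cost, bel_full, model$startle_costs, coding = "full",
      n_grid = model$n_grid, tol = model$tol)
    opt_exp <- optimal_startle_magnitude_model(
      model$blow_cost, bel_exp, model$startle_costs, coding = "expectation",
      n_grid = model$n_grid, tol = model$tol)
    rec[i, ] <- c(p_assoc, b_sparse, p_post, opt_full$r0, opt_exp$r0,
                  opt_full$c0, opt_exp$c0,
                  startle_side_cost(model$startle_costs, opt_exp$r0) +
                    expected_blow_cost_full(model$blow_cost, bel_full,
                                            opt_exp$r0))
    st <- update_association(st, tr)
  }

  out <- data.frame(trial = trials$trial, phase = trials$phase, cs = trials$cs,
                    us = as.integer(trials$us_present),
                    b = trials$us_magnitude, as.data.frame(rec))
  if (model$noise_sd > 0) {
    set.seed(protocol$seed)
    out$r_obs_full <- out$r0_full * stats::rlnorm(n, 0, model$noise_sd)
    out$r_obs_exp <- out$r0_exp * stats::rlnorm(n, 0, model$noise_sd)
  }
  attr(out, "protocol") <- protocol
  attr(out, "model") <- model
  attr(out, "seed") <- protocol$seed
  attr(out, "learner") <- st
  class(out) <- c("startle_trajectory", "data.frame")
  out
}

#' Classify the shape of a startle trajectory segment
#'
#' Counts sign changes of the first differences (changes smaller than `tol`
#' in absolute value count as no change) and labels the collapsed sign
#' pattern: no rises and at least one fall is `"monotone-decreasing"`; a
#' single rising run followed by a single falling run is
#' `"rise-then-fall"`; all differences below tolerance is `"flat"`; a single
#' rising run is `"monotone-increasing"`; anything else is `"other"`.
#'
#' @param r0 Numeric series of optimal startle magnitudes.
#' @param tol Change tolerance.
#' @return A single string label.
#' @export
classify_trajectory_shape <- function(r0, tol = 1e-6) {
  if (!is.numeric(r0) || length(r0) < 2) return("flat")
  d <- diff(r0)
  s <- sign(d) * (abs(d) > tol)
  s <- s[s != 0]
  pattern <- rle(s)$values
  if (!length(pattern)) return("flat")
  if (identical(pattern, -1)) return("monotone-decreasing")
  if (identical(pattern, 1)) return("monotone-increasing")
  if (identical(pattern, c(1, -1))) return("rise-then-fall")
  "other"
}

#' Medium- versus high-magnitude US conditioning comparison
#'
#' Runs the paired conditioning/extinction simulation that separates the
#' expectation-coded approximation from the full-distribution computation:
#' one group is conditioned with a US magnitude below the startle's
#' effectiveness cutoff (`medium_b`), the other inside the
#' ineffectiveness range (`high_b`). Under expectation coding the high
#' group's sparse magnitude expectation decays through the cutoff during
#' extinction, so its startle first *rises* and then falls, while the
#' medium group's startle decreases monotonically; under full-distribution
#' coding no rise occurs and the chosen startle is never costlier (in the
#' true objective) than the expectation-coded one.
#'
#' @param medium_b,high_b US magnitudes; `high_b` must lie inside an
#'   effectiveness-violation interval of the blow cost and `medium_b` below
#'   every such interval, else a configuration error names the violated
#'   condition.
#' @param n_acquisition,n_extinction Protocol lengths.
#' @param model A [startle_model()].
#' @param rule,rule_params,seed Passed to [conditioning_protocol()].
#' @return A list of class `davis_astrachan` with the two trajectories
#'   (`medium`, `high`), a `shapes` data frame (extinction-segment label per
#'   group and coding), and the violation ranges used for the checks.
#' @export
davis_astrachan_scenario <- function(medium_b = 1.2, high_b = 3,
                                     n_acquisition = 10, n_extinction = 30,
                                     model = startle_model(),
                                     rule = "beta-bernoulli",
                                     rule_params = list(), seed = 1L) {
  stopifnot(inherits(model, "startle_model"))
  vr <- effectiveness_violation_ranges(
    model$blow_cost,
    r_domain = c(0, model$startle_costs$r_max),
    b_domain = c(min(medium_b, high_b) / 20, max(medium_b, high_b) * 2),
    n_grid = 201L)
  if (!nrow(vr))
    stop("configuration error: blow cost has no effectiveness-violation range")
  if (!any(high_b >= vr$b_lo & high_b <= vr$b_hi))
    stop("configuration error: high_b does not lie inside a violation interval")
  if (medium_b >= min(vr$b_lo))
    stop("configuration error: medium_b does not lie below the violation ranges")

  run_group <- function(b) {
    run_protocol(conditioning_protocol(n_acquisition, n_extinction, b,
                                       rule = rule, rule_params = rule_params,
                                       seed = seed),
                 model)
  }
  medium <- run_group(medium_b)
  high <- run_group(high_b)

  ext <- function(traj, col) traj[[col]][traj$phase == "extinction"]
  shapes <- data.frame(
    group = rep(c("medium", "high"), each = 2),
    coding = rep(c("expectation", "full"), 2),
    shape = c(classify_trajectory_shape(ext(medium, "r0_exp")),
              classify_trajectory_shape(ext(medium, "r0_full")),
              classify_trajectory_shape(ext(high, "r0_exp")),
              classify_trajectory_shape(ext(high, "r0_full"))))
  structure(list(medium = medium, high = high, shapes = shapes,
                 violation_ranges = vr,
                 config = list(medium_b = medium_b, high_b = high_b,
                               n_acquisition = n_acquisition,
                               n_extinction = n_extinction, rule = rule,
                               seed = seed)),
            class = "davis_astrachan")
}

#' @export
print.davis_astrachan <- function(x, ...) {
  cat(sprintf("<davis_astrachan> medium_b = %g, high_b = %g, %d + %d trials\n",
              x$config$medium_b, x$config$high_b,
              x$config$n_acquisition, x$config$n_extinction))
  print(x$shapes, row.names = FALSE)
  invisible(x)
}
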