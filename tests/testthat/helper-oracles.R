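# Independent oracles and random-case generators for the property harnesses.
# The grid-search oracle is deliberately naive (exhaustive lattice argmin,
# first index on ties) and shares no code with the package solver.

oracle_grid_r0 <- function(f, r_max = 1, n = 1e4L) {
  g <- seq(0, r_max, length.out = n)
  g[which.min(f(g))]
}

oracle_r0_family <- function(family, p, n = 1e4L) {
  oracle_grid_r0(function(r) total_cost(family, p, r), family$r_max, n)
}

# closed-form reduced family: C_R = r^2, C_B = 1 - r on [0, 1]; true
# minimiser of r^2 + p (1 - r) is r0 = p / 2
reduced_quadratic_family <- function() {
  make_cost_family("custom",
                   params = list(c_r_direct = function(r) r^2,
                                 c_b_direct = function(r) 1 - r))
}

# forward models for the CS-alone contract: probes are rare (P(S) small) and
# associations bounded so that P(B|CS)/P(not S) <= 1
random_cs_alone_forward_model <- function() {
  forward_model(p_s_given_b = stats::runif(1, 0.9, 1),
                p_s = stats::runif(1, 0.05, 0.1),
                p_b_given_cs = stats::runif(1, 0, 0.85),
                p_b_prior = stats::runif(1, 0, 0.3))
}

random_magnitude_belief <- function(max_points = 32L, b_max = 4) {
  k <- sample(2:max_points, 1L)
  support <- sort(stats::runif(k, 0.01, b_max))
  w <- stats::rexp(k)
  magnitude_belief(support, w / sum(w) * stats::runif(1, 0.05, 1))
}

# embeds a discrete-model family's blow side as a bivariate cost that is
# linear in b; with a point mass at b = 1 the continuous model reproduces
# the discrete objective exactly
embed_family_as_bivariate <- function(family) {
  eta <- family$eta
  f <- family$fns
  bivariate_blow_cost(
    function(r, b) b * (f$c_b_direct(r) + eta * f$c_b_forgone(r)),
    r_max = family$r_max)
}
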