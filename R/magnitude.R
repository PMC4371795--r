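#' Belief over a continuous (scalar) blow magnitude
#'
#' Discretised probability mass over blow magnitudes \eqn{b \ge 0}. The mass
#' may sum to less than one: the remainder is the no-blow outcome, identified
#' with \eqn{b = 0} (at which every blow cost vanishes). `mean_b` is the
#' expectation of \eqn{b} *conditional on a blow occurring*; `p_blow` is the
#' total blow mass. A point-mass belief recovers the discrete
#' (occurrence-only) model.
#'
#' @param support Numeric vector of blow magnitudes, all `>= 0`.
#' @param probs Probability mass on `support`, non-negative, summing to at
#'   most 1.
#' @return An object of class `magnitude_belief` with fields `support`,
#'   `probs`, `p_blow`, `mean_b` (`NA` when the blow mass is zero).
#' @seealso [point_mass_belief()], [expected_blow_cost_full()]
#' @export
magnitude_belief <- function(support, probs) {
  if (!is.numeric(support) || !length(support) || any(!is.finite(support)) ||
      any(support < 0))
    stop("`support` must be finite non-negative magnitudes")
  if (!is.numeric(probs) || length(probs) != length(support) ||
      any(!is.finite(probs)) || any(probs < 0))
    stop("`probs` must be non-negative, same length as `support`")
  mass <- sum(probs)
  if (mass > 1 + 1e-9)
    stop(sprintf("total blow mass %.6g exceeds 1", mass))
  mean_b <- if (mass > 0) sum(support * probs) / mass else NA_real_
  structure(list(support = support, probs = probs,
                 p_blow = min(mass, 1), mean_b = mean_b),
            class = "magnitude_belief")
}

#' Point-mass magnitude belief
#'
#' Convenience constructor: all blow mass `p_blow` at a single magnitude
#' `b0`. With such a belief the continuous model reduces exactly to the
#' discrete model with \eqn{C_B(r) = c_b(r, b_0)}.
#'
#' @param b0 Blow magnitude (`>= 0`).
#' @param p_blow Blow probability in `[0, 1]`.
#' @return A [magnitude_belief()].
#' @export
point_mass_belief <- function(b0, p_blow) {
  magnitude_belief(support = b0, probs = p_blow)
}

#' @export
print.magnitude_belief <- function(x, ...) {
  cat(sprintf("<magnitude_belief> %d support point(s), P(blow) = %.4g, E[b | blow] = %.4g\n",
              length(x$support), x$p_blow, x$mean_b))
  invisible(x)
}

#' Bivariate blow-cost function
#'
#' Wraps a function \eqn{c_B(r, b)} giving the (direct plus opportunity)
#' cost of a blow of magnitude \eqn{b} when the startle magnitude is
#' \eqn{r}. The no-blow outcome costs nothing: \eqn{c_B(r, 0) = 0} for all
#' `r`, which is verified at construction on a probe grid.
#'
#' @param fn A function of `(r, b)`, vectorised with recycling.
#' @param r_max Upper end of the startle domain used for the probe check.
#' @param form Optional name of a registered parametric form (used for
#'   serialisation); `"custom"` otherwise.
#' @param params Optional named parameter list matching `form`.
#' @return An object of class `bivariate_blow_cost`.
#' @seealso [saturating_protection_cost()]
#' @export
bivariate_blow_cost <- function(fn, r_max = 1, form = "custom", params = list()) {
  if (!is.function(fn)) stop("`fn` must be a function of (r, b)")
  r_probe <- seq(0, r_max, length.out = 17)
  v0 <- fn(r_probe, 0)
  if (any(!is.finite(v0)) || any(abs(v0) > 1e-12))
    stop("blow cost must vanish at b = 0 (no blow, no blow cost)")
  structure(list(fn = fn, r_max = r_max, form = form, params = params),
            class = "bivariate_blow_cost")
}

#' @export
print.bivariate_blow_cost <- function(x, ...) {
  cat(sprintf("<bivariate_blow_cost> form = '%s'\n", x$form))
  invisible(x)
}

#' Saturating-protection blow cost
#'
#' The shipped bivariate form
#' \deqn{c_B(r, b) = b\,[1 - g_{\max}\, r \cdot \mathbf{1}\{b \le b_{crit}\}],}
#' in which the startle response removes a fraction `g_max * r` of the blow
#' cost (protection increasing in `r`) as long as the blow magnitude stays
#' at or below the effectiveness plateau `b_crit`; above `b_crit` protection
#' vanishes and the startle no longer reduces the cost. This is the minimal
#' form exhibiting both the compliant regime (blow cost strictly decreasing
#' in `r`) and the violation regime (\eqn{\partial c_B/\partial r \ge 0} for
#' `b > b_crit`) that the medium- versus high-magnitude footshock
#' dissociation requires.
#'
#' @param g_max Maximal protected fraction at `r = r_max`; in `[0, 1]`.
#' @param b_crit Effectiveness cutoff magnitude.
#' @param r_max Startle domain upper bound.
#' @return A [bivariate_blow_cost()].
#' @export
saturating_protection_cost <- function(g_max = 0.8, b_crit = 2, r_max = 1) {
  if (!is.numeric(g_max) || g_max < 0 || g_max * r_max > 1)
    stop("`g_max * r_max` must lie in [0, 1]")
  if (!is.numeric(b_crit) || b_crit <= 0) stop("`b_crit` must be positive")
  force(g_max); force(b_crit)
  bivariate_blow_cost(
    function(r, b) b * (1 - g_max * r * (b <= b_crit)),
    r_max = r_max,
    form = "saturating-protection",
    params = list(g_max = g_max, b_crit = b_crit))
}

#' Expected blow cost under the full magnitude distribution
#'
#' The normative blow-cost functional: the bivariate cost integrated over
#' the whole belief, \eqn{\sum_b p(B = b)\, c_B(r, b)}. The no-blow mass
#' contributes nothing since \eqn{c_B(r, 0) = 0}.
#'
#' @param cost A [bivariate_blow_cost()].
#' @param belief A [magnitude_belief()].
#' @param r Startle magnitude(s); vectorised.
#' @return Numeric vector of expected blow costs.
#' @export
expected_blow_cost_full <- function(cost, belief, r) {
  stopifnot(inherits(cost, "bivariate_blow_cost"),
            inherits(belief, "magnitude_belief"))
  if (!is.numeric(r) || any(!is.finite(r))) stop("`r` must be finite numeric")
  if (!length(belief$support) || belief$p_blow == 0) return(rep(0, length(r)))
  M <- outer(r, belief$support, cost$fn)
  v <- drop(M %*% belief$probs)
  if (any(!is.finite(v))) stop("non-finite blow cost on the belief support")
  v
}

#' Expected blow cost under expectation coding
#'
#' The sparse approximation in which only the expected blow magnitude, not
#' the full distribution, reaches the cost function:
#' \eqn{P(blow)\, c_B(r, E[b \mid blow])}. It coincides with
#' [expected_blow_cost_full()] whenever \eqn{c_B} is linear in \eqn{b}
#' (linearity of expectation) and in particular for point-mass beliefs; for
#' nonlinear costs it mis-estimates the true expectation (Jensen's
#' inequality gives the direction).
#'
#' @inheritParams expected_blow_cost_full
#' @return Numeric vector; 0 when the belief carries no blow mass (no
#'   expectation is defined; a message is emitted).
#' @export
expected_blow_cost_expectation_coded <- function(cost, belief, r) {
  stopifnot(inherits(cost, "bivariate_blow_cost"),
            inherits(belief, "magnitude_belief"))
  if (!is.numeric(r) || any(!is.finite(r))) stop("`r` must be finite numeric")
  if (belief$p_blow == 0 || is.na(belief$mean_b)) {
    message("magnitude belief has zero blow mass; expectation-coded cost is 0")
    return(rep(0, length(r)))
  }
  v <- belief$p_blow * cost$fn(r, belief$mean_b)
  if (any(!is.finite(v))) stop("non-finite blow cost at the expected magnitude")
  v
}

#' Cost-minimising startle under the continuous blow-magnitude model
#'
#' Minimises the startle-side costs of `startle_costs` (its direct and
#' `eta`-scaled opportunity startle terms; the family's own blow components
#' are ignored here) plus the chosen blow-cost functional over
#' `[0, r_max]`, with the same grid-plus-refinement contract as
#' [optimal_startle()].
#'
#' @inheritParams expected_blow_cost_full
#' @param startle_costs A [cost_family][make_cost_family] supplying
#'   `c_r_direct`, `c_r_forgone` and `eta`.
#' @param coding `"full"` for the full-distribution functional,
#'   `"expectation"` for the expectation-coded approximation.
#' @param n_grid,tol Solver settings as in [optimal_startle()].
#' @return A `startle_optimum` with an additional `coding` field.
#' @export
optimal_startle_magnitude_model <- function(cost, belief, startle_costs,
                                            coding = c("full", "expectation"),
                                            n_grid = 1024L, tol = 1e-8) {
  coding <- match.arg(coding)
  stopifnot(inherits(startle_costs, "cost_family"))
  blow_fun <- switch(coding,
    full = function(r) expected_blow_cost_full(cost, belief, r),
    expectation = function(r)
      suppressMessages(expected_blow_cost_expectation_coded(cost, belief, r)))
  objective <- function(r)
    startle_side_cost(startle_costs, r) + blow_fun(r)
  opt <- .minimise_over_r(objective, startle_costs$r_max,
                          n_grid = n_grid, tol = tol)
  opt$coding <- coding
  opt
}

#' Startle-side cost of a family
#'
#' The startle-response part of the total cost,
#' \eqn{C_{R,d}(r) + \eta C_{R,f}(r)}, used as the `r`-dependent base cost in
#' the continuous blow-magnitude model.
#'
#' @inheritParams total_cost
#' @return Numeric vector, same length as `r`.
#' @export
startle_side_cost <- function(family, r) {
  stopifnot(inherits(family, "cost_family"))
  family$fns$c_r_direct(r) + family$eta * family$fns$c_r_forgone(r)
}

#' Blow-magnitude ranges where the startle loses effectiveness
#'
#' Scans an `(r, b)` lattice for violations of the effectiveness condition
#' of the continuous model — startle must reduce the blow cost, i.e.
#' \eqn{\partial c_B/\partial r < 0}. Returns the maximal `b`-intervals on
#' the grid in which the numeric derivative is `>= 0` for some `r` in
#' `r_domain`. Inside such intervals a stronger expected blow no longer
#' recruits a stronger startle, which is what lets the expectation-coded
#' simulator reproduce the high-magnitude footshock anomalies.
#'
#' @param cost A [bivariate_blow_cost()].
#' @param r_domain Length-2 startle range; a single point (zero width) is a
#'   documented degenerate case returning no intervals.
#' @param b_domain Length-2 positive blow-magnitude range. The lower end
#'   must be positive: at `b = 0` every blow cost is identically zero and no
#'   effectiveness is defined.
#' @param n_grid Lattice points per axis (`>= 3`).
#' @return A data frame with columns `b_lo`, `b_hi`, one row per maximal
#'   violating interval (zero rows when the startle is effective
#'   everywhere).
#' @examples
#' effectiveness_violation_ranges(saturating_protection_cost(b_crit = 2),
#'                                b_domain = c(0.1, 4))
#' @export
effectiveness_violation_ranges <- function(cost, r_domain = c(0, 1),
                                           b_domain = c(0.05, 4),
                                           n_grid = 101L) {
  stopifnot(inherits(cost, "bivariate_blow_cost"))
  if (!is.numeric(r_domain) || length(r_domain) != 2L || r_domain[1] > r_domain[2])
    stop("`r_domain` must be an ordered length-2 range")
  if (!is.numeric(b_domain) || length(b_domain) != 2L ||
      b_domain[1] <= 0 || b_domain[1] >= b_domain[2])
    stop("`b_domain` must be an ordered length-2 range with positive lower end")
  if (n_grid < 3) stop("`n_grid` must be >= 3 per axis")
  n_grid <- as.integer(n_grid)
  if (diff(r_domain) == 0) {
    message("r_domain has zero width; no derivative defined, returning no intervals")
    return(data.frame(b_lo = numeric(0), b_hi = numeric(0)))
  }
  h <- diff(r_domain) / (10 * n_grid)
  r <- seq(r_domain[1] + h, r_domain[2] - h, length.out = n_grid)
  b <- seq(b_domain[1], b_domain[2], length.out = n_grid)
  violating <- vapply(b, function(bj) {
    dv <- (cost$fn(r + h, bj) - cost$fn(r - h, bj)) / (2 * h)
    if (any(!is.finite(dv))) stop("non-finite blow-cost derivative")
    any(dv >= -1e-10)
  }, logical(1))
  runs <- rle(violating)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(b_lo = b[starts[keep]], b_hi = b[ends[keep]])
}
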