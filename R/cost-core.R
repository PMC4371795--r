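#' Belief about blow occurrence
#'
#' Wraps the probability \eqn{P(B|X)} that a blow occurs given the current
#' sensory input, the quantity driving the expected-blow-cost term of the
#' total cost. In the discrete model the blow is Bernoulli: it occurs or not.
#'
#' @param p_blow Probability in `[0, 1]`.
#' @return An object of class `blow_belief`.
#' @export
blow_belief <- function(p_blow) {
  if (!is.numeric(p_blow) || length(p_blow) != 1L || !is.finite(p_blow) ||
      p_blow < 0 || p_blow > 1)
    stop("`p_blow` must be a single probability in [0, 1]")
  structure(list(p_blow = p_blow), class = "blow_belief")
}

#' @export
print.blow_belief <- function(x, ...) {
  cat(sprintf("<blow_belief> P(B|X) = %g\n", x$p_blow))
  invisible(x)
}

.as_p_blow <- function(belief) {
  if (inherits(belief, "blow_belief")) return(belief$p_blow)
  if (is.numeric(belief) && length(belief) == 1L && is.finite(belief) &&
      belief >= 0 && belief <= 1)
    return(belief)
  stop("`belief` must be a blow_belief or a probability in [0, 1]")
}

#' Total expected cost of a startle response
#'
#' Evaluates the additive cost model
#' \deqn{C_{TOT}(r) = C_{R,d}(r) + \eta C_{R,f}(r) +
#'       P(B|X)\,[C_{B,d}(r) + \eta C_{B,f}(r)],}
#' the sum of the startle-response cost and the expected cost of the blow
#' under the Bernoulli blow belief. The value is affine in `p_blow` and in
#' `eta` at fixed `r`.
#'
#' @param family A [cost_family][make_cost_family].
#' @param belief A [blow_belief()] or a bare probability in `[0, 1]`.
#' @param r Startle magnitude(s) in `[0, r_max]`; vectorised.
#' @return Numeric vector of non-negative finite costs, same length as `r`.
#' @examples
#' fam <- make_cost_family("custom",
#'   params = list(c_r_direct = function(r) r^2,
#'                 c_b_direct = function(r) 1 - r))
#' total_cost(fam, 0.5, 0.5)  # 0.25 + 0.5 * 0.5 = 0.5
#' @export
total_cost <- function(family, belief, r) {
  stopifnot(inherits(family, "cost_family"))
  p <- .as_p_blow(belief)
  if (!is.numeric(r) || any(!is.finite(r)))
    stop("`r` must be finite numeric")
  if (any(r < 0 | r > family$r_max))
    stop(sprintf("startle magnitude r outside domain [0, %g]", family$r_max))
  comp <- lapply(.component_names, function(nm) {
    v <- family$fns[[nm]](r)
    if (any(!is.finite(v)))
      stop(sprintf("component '%s' evaluated to a non-finite value", nm))
    v
  })
  names(comp) <- .component_names
  comp$c_r_direct + family$eta * comp$c_r_forgone +
    p * (comp$c_b_direct + family$eta * comp$c_b_forgone)
}

# Grid-first bounded minimisation over r in [0, r_max]: evaluate `f` on a
# coarse lattice, then refine around the best lattice point with
# stats::optimize. The refined point is kept only when it strictly improves
# on the lattice minimum, so on plateaus the smallest r wins (ties resolve
# low). Theorems about the model concern *global* minimisers, hence the
# lattice stage guards against local traps for non-convex families.
.minimise_over_r <- function(f, r_max, n_grid = 1024L, tol = 1e-8) {
  grid <- seq(0, r_max, length.out = n_grid)
  cv <- f(grid)
  if (any(!is.finite(cv)))
    stop("non-finite cost on the evaluation grid; cannot minimise")
  i <- which.min(cv)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  r0 <- grid[i]
  c0 <- cv[i]
  if (hi > lo) {
    op <- stats::optimize(f, lower = lo, upper = hi, tol = tol)
    if (is.finite(op$objective) && op$objective < c0) {
      r0 <- op$minimum
      c0 <- op$objective
    }
  }
  structure(list(r0 = r0, c0 = c0, n_grid = n_grid, tol = tol),
            class = "startle_optimum")
}

#' @export
print.startle_optimum <- function(x, ...) {
  cat(sprintf("<startle_optimum> r0 = %.6g, cost = %.6g\n", x$r0, x$c0))
  invisible(x)
}

#' Cost-minimising startle magnitude
#'
#' Finds the global minimiser \eqn{r_0} of [total_cost()] over
#' `[0, r_max]` by a coarse grid search (default 1024 points) followed by
#' bounded scalar refinement around the best grid point. When the minimum is
#' attained on a set, the smallest `r` is returned.
#'
#' Two monotonicity results follow from the model's assumptions and are
#' enforced by the test suite: raising the blow probability never lowers
#' \eqn{r_0}, and raising the opportunity-cost scale `eta` never lowers
#' \eqn{r_0} (the latter within the applicability range of the
#' opportunity-slope assumption, see [applicable_p_floor()]).
#'
#' @inheritParams total_cost
#' @param n_grid Number of lattice points for the global stage.
#' @param tol Refinement tolerance on `r`.
#' @param check_assumptions If `TRUE` (default), run [audit_assumptions()]
#'   first and error when the family violates the model's assumptions; pass
#'   `FALSE` to waive the audit explicitly (e.g. for reduced families with no
#'   opportunity costs).
#' @return A `startle_optimum` with fields `r0` (minimiser) and `c0` (its
#'   total cost).
#' @examples
#' fam <- make_cost_family("custom",
#'   params = list(c_r_direct = function(r) r^2,
#'                 c_b_direct = function(r) 1 - r))
#' optimal_startle(fam, 0.6, check_assumptions = FALSE)$r0  # p/2 = 0.3
#' @export
optimal_startle <- function(family, belief, n_grid = 1024L, tol = 1e-8,
                            check_assumptions = TRUE) {
  stopifnot(inherits(family, "cost_family"))
  p <- .as_p_blow(belief)
  if (isTRUE(check_assumptions)) {
    rep <- audit_assumptions(family, n_grid = 41L)
    if (!all(rep$passed))
      stop(paste0("cost family violates model assumption(s): ",
                  paste(rep$assumption[!rep$passed], collapse = ", "),
                  "; pass check_assumptions = FALSE to waive"))
  }
  .minimise_over_r(function(r) total_cost(family, p, r),
                   family$r_max, n_grid = n_grid, tol = tol)
}
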