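#' Numerically audit the behavioural assumptions of a cost family
#'
#' The cost model rests on four assumptions. Two are structural and hold by
#' construction here: costs combine additively (the object *is* an additive
#' family) and the opportunity scale `eta` multiplies both opportunity terms
#' jointly. The other two constrain derivatives and are checked by central
#' differences on an `n_grid` lattice over `[0, r_max]`:
#'
#' * **Blow cost decreasing**: a more vigorous startle reduces the cost of a
#'   blow (but never its probability):
#'   \eqn{\frac{d}{dr}[C_{B,d}(r) + \eta C_{B,f}(r)] < 0}.
#' * **Opportunity slopes**: \eqn{C_{R,f}' > 0}, \eqn{C_{B,f}' < 0}, and the
#'   rise of the startle opportunity cost is shallower than the fall of the
#'   blow opportunity cost: \eqn{|C_{R,f}'| < p_{\min}\,|C_{B,f}'|}. With the
#'   default `p_min = 1` this is the literal slope comparison; supplying the
#'   smallest blow probability at which the model will be applied checks the
#'   expectation-weighted condition that the opportunity-cost monotonicity
#'   theorem actually uses (see [applicable_p_floor()]).
#'
#' Strict inequalities are enforced with margin `1e-10`; derivative steps are
#' `r_max / (10 * n_grid)`.
#'
#' @param family A [cost_family][make_cost_family].
#' @param n_grid Number of lattice points (`>= 3`).
#' @param p_min Blow-probability weight for the slope comparison (default 1).
#' @return An `assumption_report`: a data frame with one row per assumption
#'   (`assumption`, `passed`, `worst_r`, `margin`). `margin` is the smallest
#'   slack observed (negative when violated); `worst_r` locates it.
#' @examples
#' audit_assumptions(make_cost_family())
#' @export
audit_assumptions <- function(family, n_grid = 101L, p_min = 1) {
  stopifnot(inherits(family, "cost_family"))
  if (!is.numeric(n_grid) || length(n_grid) != 1L || n_grid < 3)
    stop("`n_grid` must be >= 3")
  if (!is.numeric(p_min) || length(p_min) != 1L || !is.finite(p_min) ||
      p_min < 0 || p_min > 1)
    stop("`p_min` must be a probability in [0, 1]")
  n_grid <- as.integer(n_grid)
  h <- family$r_max / (10 * n_grid)
  r <- seq(h, family$r_max - h, length.out = n_grid)
  margin <- 1e-10

  d <- function(nm) {
    (family$fns[[nm]](r + h) - family$fns[[nm]](r - h)) / (2 * h)
  }
  d_rf <- d("c_r_forgone")
  d_bf <- d("c_b_forgone")
  d_blow <- d("c_b_direct") + family$eta * d_bf

  # each check: slack vector that must stay strictly positive
  checks <- list(
    additivity = NULL,                       # structural
    blow_cost_decreasing = -d_blow - margin,
    opportunity_scaling = NULL,              # structural
    opportunity_slopes = pmin(d_rf - margin,
                              -d_bf - margin,
                              p_min * abs(d_bf) - abs(d_rf) - margin))

  rows <- lapply(names(checks), function(nm) {
    slack <- checks[[nm]]
    if (is.null(slack))
      return(data.frame(assumption = nm, passed = TRUE,
                        worst_r = NA_real_, margin = NA_real_))
    i <- which.min(slack)
    data.frame(assumption = nm, passed = all(slack > 0),
               worst_r = r[i], margin = slack[i] + margin)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_grid") <- n_grid
  attr(out, "p_min") <- p_min
  attr(out, "step") <- h
  class(out) <- c("assumption_report", "data.frame")
  out
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("<assumption_report> n_grid = %d, p_min = %g\n",
              attr(x, "n_grid"), attr(x, "p_min")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Does a cost family pass the assumption audit?
#'
#' @inheritParams audit_assumptions
#' @return `TRUE` if every assumption in [audit_assumptions()] passes.
#' @export
family_passes_audit <- function(family, n_grid = 101L, p_min = 1) {
  all(audit_assumptions(family, n_grid = n_grid, p_min = p_min)$passed)
}

#' Smallest blow probability at which eta-monotonicity is guaranteed
#'
#' The opportunity-cost monotonicity result (raising `eta` never lowers the
#' optimal startle magnitude) requires the *expected* blow opportunity cost
#' to fall faster than the startle opportunity cost rises, i.e.
#' \eqn{|C_{R,f}'(r)| < P(B|X)\,|C_{B,f}'(r)|} over the whole domain. This
#' returns the ratio \eqn{\max_r |C_{R,f}'| / \min_r |C_{B,f}'|}: for blow
#' probabilities strictly above it the condition holds everywhere; below it,
#' raising `eta` can lower the optimum because the startle-side opportunity
#' cost dominates.
#'
#' @inheritParams audit_assumptions
#' @return A single number (may exceed 1, meaning no probability qualifies).
#' @export
applicable_p_floor <- function(family, n_grid = 101L) {
  stopifnot(inherits(family, "cost_family"))
  n_grid <- as.integer(n_grid)
  h <- family$r_max / (10 * n_grid)
  r <- seq(h, family$r_max - h, length.out = n_grid)
  d_rf <- (family$fns$c_r_forgone(r + h) - family$fns$c_r_forgone(r - h)) / (2 * h)
  d_bf <- (family$fns$c_b_forgone(r + h) - family$fns$c_b_forgone(r - h)) / (2 * h)
  mn <- min(abs(d_bf))
  if (mn == 0) return(Inf)
  max(abs(d_rf)) / mn
}
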