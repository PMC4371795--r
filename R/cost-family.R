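#' Construct a startle/blow cost family
#'
#' A cost family bundles the four cost components of the additive startle
#' decision model on the startle-magnitude interval `[0, r_max]`:
#'
#' * `c_r_direct`: \eqn{C_{R,d}(r)}, the direct (metabolic) cost of a startle
#'   response of magnitude \eqn{r};
#' * `c_r_forgone`: \eqn{C_{R,f}(r)}, the opportunity cost of the startle
#'   response (benefits forgone because ongoing behaviour is interrupted);
#' * `c_b_direct`: \eqn{C_{B,d}(r)}, the direct cost of a blow given that one
#'   occurs (e.g. tissue damage), decreasing in \eqn{r} because a more vigorous
#'   startle protects better;
#' * `c_b_forgone`: \eqn{C_{B,f}(r)}, the opportunity cost of the blow.
#'
#' The scalar `eta` (\eqn{\eta \ge 0}) multiplies both opportunity-cost terms
#' jointly and models a change in the utility of the behaviour that a startle
#' or a blow would interrupt (e.g. reward anticipation raises `eta`).
#'
#' Three parametric forms are registered, plus `"custom"`:
#'
#' * `"quadratic-exponential"` (default): \eqn{C_{R,d} = a_{rd} r^2},
#'   \eqn{C_{R,f} = a_{rf} r}, \eqn{C_{B,d} = s_{bd} e^{-k_{bd} r}},
#'   \eqn{C_{B,f} = s_{bf} e^{-k_{bf} r}} — convex rising startle cost and
#'   decaying blow cost.
#' * `"linear"`: all four components affine in `r`; blow costs are clipped-free
#'   (parameters must keep them non-negative at `r_max`).
#' * `"logistic"`: sigmoid direct costs, linear startle opportunity cost,
#'   sigmoid blow opportunity cost.
#' * `"custom"`: supply the four component functions (vectorised over `r`)
#'   directly in `params`; missing components default to zero.
#'
#' Construction validates finiteness and non-negativity on a probe grid but
#' does **not** guarantee that the model's behavioural assumptions hold; run
#' [audit_assumptions()] for that.
#'
#' @param form Name of a registered parametric form, or `"custom"`.
#' @param params Named list of parameters overriding the form's defaults; for
#'   `"custom"`, a named list of functions `c_r_direct`, `c_r_forgone`,
#'   `c_b_direct`, `c_b_forgone`.
#' @param eta Opportunity-cost scale factor, `eta >= 0`. `eta = 1` is the
#'   baseline model.
#' @param r_max Upper end of the startle-magnitude domain `[0, r_max]`;
#'   `r` is unitless response vigour normalised so that `r_max = 1` by default.
#'
#' @return An object of class `cost_family`.
#' @examples
#' fam <- make_cost_family()
#' total_cost(fam, blow_belief(0.5), 0.3)
#' audit_assumptions(fam)
#' @seealso [total_cost()], [optimal_startle()], [audit_assumptions()],
#'   [scale_opportunity()]
#' @export
make_cost_family <- function(form = "quadratic-exponential", params = list(),
                             eta = 1, r_max = 1) {
  if (!is.character(form) || length(form) != 1L)
    stop("`form` must be a single form name")
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 0)
    stop("`eta` must be a single non-negative number")
  if (!is.numeric(r_max) || length(r_max) != 1L || !is.finite(r_max) || r_max <= 0)
    stop("`r_max` must be a single positive number")

  if (form == "custom") {
    fns <- .custom_components(params)
    params_out <- list()
  } else {
    reg <- .cost_forms[[form]]
    if (is.null(reg))
      stop(sprintf("unknown cost-family form '%s'; registered forms: %s",
                   form, paste(c(names(.cost_forms), "custom"), collapse = ", ")))
    unknown <- setdiff(names(params), names(reg$defaults))
    if (length(unknown))
      stop(sprintf("unknown parameter(s) for form '%s': %s",
                   form, paste(unknown, collapse = ", ")))
    p <- utils::modifyList(reg$defaults, params)
    reg$check(p, r_max)
    fns <- reg$build(p, r_max)
    params_out <- p
  }

  fam <- structure(
    list(form = form, params = params_out, fns = fns, eta = eta, r_max = r_max),
    class = "cost_family")
  .validate_components(fam)
  fam
}

# registered parametric forms; `check` rejects parameters that would produce
# negative or non-finite costs, `build` returns the four component closures
.cost_forms <- list(
  "quadratic-exponential" = list(
    defaults = list(a_rd = 1, a_rf = 0.1, s_bd = 1, k_bd = 2, s_bf = 1.5, k_bf = 1),
    check = function(p, r_max) {
      sc <- unlist(p)
      if (any(!is.finite(sc))) stop("non-finite cost-family parameter")
      if (any(unlist(p[c("a_rd", "a_rf", "s_bd", "s_bf")]) < 0))
        stop("cost scales must be non-negative")
    },
    build = function(p, r_max) list(
      c_r_direct  = function(r) p$a_rd * r^2,
      c_r_forgone = function(r) p$a_rf * r,
      c_b_direct  = function(r) p$s_bd * exp(-p$k_bd * r),
      c_b_forgone = function(r) p$s_bf * exp(-p$k_bf * r))),
  linear = list(
    defaults = list(a_rd = 0.5, a_rf = 0.1, b_bd0 = 1, a_bd = 0.8,
                    b_bf0 = 2, a_bf = 1.5),
    check = function(p, r_max) {
      sc <- unlist(p)
      if (any(!is.finite(sc))) stop("non-finite cost-family parameter")
      if (any(sc < 0)) stop("cost scales must be non-negative")
      if (p$b_bd0 - p$a_bd * r_max < 0)
        stop("c_b_direct would be negative at r_max; increase b_bd0")
      if (p$b_bf0 - p$a_bf * r_max < 0)
        stop("c_b_forgone would be negative at r_max; increase b_bf0")
    },
    build = function(p, r_max) list(
      c_r_direct  = function(r) p$a_rd * r,
      c_r_forgone = function(r) p$a_rf * r,
      c_b_direct  = function(r) p$b_bd0 - p$a_bd * r,
      c_b_forgone = function(r) p$b_bf0 - p$a_bf * r)),
  logistic = list(
    defaults = list(s_rd = 1, k_rd = 6, a_rf = 0.05, s_bd = 1, k_bd = 6,
                    s_bf = 1.5, k_bf = 4),
    check = function(p, r_max) {
      sc <- unlist(p)
      if (any(!is.finite(sc))) stop("non-finite cost-family parameter")
      if (any(sc < 0)) stop("cost scales must be non-negative")
    },
    build = function(p, r_max) list(
      c_r_direct  = function(r) p$s_rd * stats::plogis(p$k_rd * (r - r_max / 2)),
      c_r_forgone = function(r) p$a_rf * r,
      c_b_direct  = function(r) p$s_bd * stats::plogis(-p$k_bd * (r - r_max / 2)),
      c_b_forgone = function(r) p$s_bf * stats::plogis(-p$k_bf * (r - r_max / 2)))))

.component_names <- c("c_r_direct", "c_r_forgone", "c_b_direct", "c_b_forgone")

.custom_components <- function(params) {
  unknown <- setdiff(names(params), .component_names)
  if (length(unknown))
    stop(sprintf("unknown custom component(s): %s", paste(unknown, collapse = ", ")))
  zero <- function(r) rep(0, length(r))
  fns <- stats::setNames(
    lapply(.component_names, function(nm) {
      f <- params[[nm]]
      if (is.null(f)) return(zero)
      if (!is.function(f)) stop(sprintf("custom component '%s' must be a function", nm))
      f
    }), .component_names)
  fns
}

.validate_components <- function(fam, n_probe = 64L) {
  r <- seq(0, fam$r_max, length.out = n_probe)
  for (nm in .component_names) {
    v <- fam$fns[[nm]](r)
    if (length(v) != length(r))
      stop(sprintf("component '%s' does not vectorise over r", nm))
    if (any(!is.finite(v)))
      stop(sprintf("component '%s' is non-finite on [0, r_max]", nm))
    if (any(v < -1e-12))
      stop(sprintf("component '%s' is negative on [0, r_max]", nm))
  }
  invisible(fam)
}

#' Rescale the opportunity-cost terms of a cost family
#'
#' Returns a family identical to `family` except that the opportunity-cost
#' scale is set to `eta_new`. The scale multiplies the startle and the blow
#' opportunity costs jointly, never separately; direct costs are untouched.
#' Raising `eta` models an increase in the utility of the interrupted ongoing
#' behaviour (reward anticipation, instructed attention); `eta_new = 0`
#' removes the opportunity terms altogether.
#'
#' @param family A [cost_family][make_cost_family].
#' @param eta_new New scale, `eta_new >= 0`.
#' @return A `cost_family` with `eta = eta_new`.
#' @export
scale_opportunity <- function(family, eta_new) {
  stopifnot(inherits(family, "cost_family"))
  if (!is.numeric(eta_new) || length(eta_new) != 1L || !is.finite(eta_new) ||
      eta_new < 0)
    stop("`eta_new` must be a single non-negative number")
  family$eta <- eta_new
  family
}

#' Draw a random cost family satisfying the model's assumptions
#'
#' Samples parameters of the `"quadratic-exponential"` or `"linear"` form from
#' ranges chosen so that the blow cost is strictly decreasing and the
#' opportunity-cost slope condition holds on the whole domain (see
#' [audit_assumptions()]). Used by the property-test and acceptance harnesses;
#' uses the current RNG state, so seed with [set.seed()] for reproducibility.
#'
#' @param form One of `"quadratic-exponential"`, `"linear"`; by default one is
#'   picked at random.
#' @param r_max Domain upper bound passed to [make_cost_family()].
#' @return A `cost_family`.
#' @export
random_cost_family <- function(form = NULL, r_max = 1) {
  if (is.null(form))
    form <- sample(c("quadratic-exponential", "linear"), 1L)
  params <- switch(
    form,
    "quadratic-exponential" = list(
      a_rd = stats::runif(1, 0.5, 2),
      a_rf = stats::runif(1, 0.01, 0.08),
      s_bd = stats::runif(1, 0.5, 2),
      k_bd = stats::runif(1, 0.5, 3),
      s_bf = stats::runif(1, 1, 3),
      k_bf = stats::runif(1, 0.5, 1.5)),
    linear = {
      a_bd <- stats::runif(1, 0.2, 1)
      a_bf <- stats::runif(1, 0.5, 2)
      list(
        a_rd = stats::runif(1, 0.2, 1),
        a_rf = stats::runif(1, 0.02, 0.3),
        b_bd0 = a_bd * r_max * stats::runif(1, 1.05, 1.5),
        a_bd = a_bd,
        b_bf0 = a_bf * r_max * stats::runif(1, 1.05, 1.5),
        a_bf = a_bf)
    },
    stop(sprintf("unsupported random form '%s'", form)))
  make_cost_family(form, params, eta = 1, r_max = r_max)
}

#' @export
print.cost_family <- function(x, ...) {
  cat(sprintf("<cost_family> form = '%s', eta = %g, r domain = [0, %g]\n",
              x$form, x$eta, x$r_max))
  if (length(x$params))
    cat("  params:", paste(sprintf("%s = %g", names(x$params),
                                   unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}
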