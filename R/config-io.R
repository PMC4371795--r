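#' Serialise model components as structured configuration
#'
#' Cost families, bivariate blow costs and protocols built from registered
#' parametric forms round-trip through plain YAML configuration files;
#' `"custom"` components built from arbitrary R closures do not, and raise
#' an error.
#'
#' @param family A [cost_family][make_cost_family] with a registered form.
#' @return `cost_family_spec()`: a plain list (`form`, `params`, `eta`,
#'   `r_max`) suitable for [yaml::write_yaml()].
#' @seealso [read_cost_family()], [write_protocol()]
#' @export
cost_family_spec <- function(family) {
  stopifnot(inherits(family, "cost_family"))
  if (family$form == "custom")
    stop("custom cost families (built from closures) are not serialisable")
  list(form = family$form, params = family$params,
       eta = family$eta, r_max = family$r_max)
}

#' @rdname cost_family_spec
#' @param spec A list as produced by `cost_family_spec()`.
#' @export
cost_family_from_spec <- function(spec) {
  need <- c("form", "params")
  if (!is.list(spec) || !all(need %in% names(spec)))
    stop("`spec` must be a list with at least `form` and `params`")
  make_cost_family(spec$form, spec$params,
                   eta = if (is.null(spec$eta)) 1 else spec$eta,
                   r_max = if (is.null(spec$r_max)) 1 else spec$r_max)
}

#' Read or write a cost-family configuration file
#'
#' @param family A [cost_family][make_cost_family] with a registered form.
#' @param path File path (YAML).
#' @return `read_cost_family()` returns a `cost_family`;
#'   `write_cost_family()` returns `path` invisibly.
#' @export
write_cost_family <- function(family, path) {
  yaml::write_yaml(cost_family_spec(family), path)
  invisible(path)
}

#' @rdname write_cost_family
#' @export
read_cost_family <- function(path) {
  cost_family_from_spec(yaml::read_yaml(path))
}

#' Serialise a bivariate blow cost
#'
#' Only registered forms (currently `"saturating-protection"`) round-trip.
#'
#' @param cost A [bivariate_blow_cost()].
#' @return A plain list (`form`, `params`, `r_max`).
#' @export
blow_cost_spec <- function(cost) {
  stopifnot(inherits(cost, "bivariate_blow_cost"))
  if (cost$form == "custom")
    stop("custom bivariate blow costs are not serialisable")
  list(form = cost$form, params = cost$params, r_max = cost$r_max)
}

#' @rdname blow_cost_spec
#' @param spec A list as produced by `blow_cost_spec()`.
#' @export
blow_cost_from_spec <- function(spec) {
  if (!is.list(spec) || is.null(spec$form))
    stop("`spec` must be a list with a `form` entry")
  if (spec$form != "saturating-protection")
    stop(sprintf("unknown blow-cost form '%s'", spec$form))
  p <- spec$params
  saturating_protection_cost(
    g_max = if (is.null(p$g_max)) 0.8 else p$g_max,
    b_crit = if (is.null(p$b_crit)) 2 else p$b_crit,
    r_max = if (is.null(spec$r_max)) 1 else spec$r_max)
}

#' Read or write a conditioning protocol file
#'
#' Protocols are stored as YAML: the learning rule, its parameters, the
#' seed, and the full ordered trial list.
#'
#' @param protocol A [startle_protocol][conditioning_protocol].
#' @param path File path (YAML).
#' @return `read_protocol()` returns a `startle_protocol`;
#'   `write_protocol()` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "startle_protocol"))
  tr <- protocol$trials
  yaml::write_yaml(list(
    rule = protocol$rule,
    rule_params = protocol$rule_params,
    seed = protocol$seed,
    trials = lapply(seq_len(nrow(tr)), function(i) as.list(tr[i, ]))),
    path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$trials)) stop("protocol file has no `trials` section")
  trials <- do.call(rbind, lapply(cfg$trials, as.data.frame))
  protocol(trials,
           rule = if (is.null(cfg$rule)) "beta-bernoulli" else cfg$rule,
           rule_params = if (is.null(cfg$rule_params)) list() else cfg$rule_params,
           seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}

#' Write a simulated trajectory as CSV with a JSON sidecar
#'
#' The CSV holds the per-trial record (columns `trial`, `phase`, `cs`, `us`,
#' `b`, `p_assoc`, `mean_b`, `p_post`, `r0_full`, `r0_exp`, `cost_full`,
#' `cost_exp`, `cost_full_at_exp`, plus observed-response columns when noise
#' is enabled). A sidecar JSON file with the same stem captures the full
#' configuration — learning rule and parameters, seed, forward-model
#' constants, cost forms and solver settings — so a run can be reproduced
#' from its artefacts.
#'
#' @param traj A `startle_trajectory` from [run_protocol()].
#' @param path CSV file path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "startle_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  prot <- attr(traj, "protocol")
  model <- attr(traj, "model")
  side <- list(
    seed = attr(traj, "seed"),
    rule = prot$rule,
    rule_params = prot$rule_params,
    n_trials = nrow(traj),
    forward = unclass(model$forward),
    p_nos_given_b = model$p_nos_given_b,
    solver = list(n_grid = model$n_grid, tol = model$tol,
                  noise_sd = model$noise_sd),
    startle_costs = tryCatch(cost_family_spec(model$startle_costs),
                             error = function(e) list(form = "custom")),
    blow_cost = tryCatch(blow_cost_spec(model$blow_cost),
                         error = function(e) list(form = "custom")))
  jsonlite::write_json(side, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
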