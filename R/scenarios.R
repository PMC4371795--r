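# Scenario catalogue: each entry turns one experimental paradigm into a
# concrete manipulation of the model (a probability, a prior, an opportunity
# scale, or a US magnitude) plus the qualitative direction the model
# predicts for the optimal startle magnitude. Directions are classified
# from r0 comparisons only, with |delta r0| < 1e-6 counting as "near-zero"
# (the solver tolerance floor).

.scenario_family <- function(params = list()) {
  make_cost_family("quadratic-exponential",
                   utils::modifyList(list(a_rd = 1, a_rf = 0.02, s_bd = 1,
                                          k_bd = 2, s_bf = 2, k_bf = 1),
                                     params))
}

.r0_at <- function(p, eta = 1, family = .scenario_family()) {
  optimal_startle(scale_opportunity(family, eta), p,
                  check_assumptions = FALSE)$r0
}

.direction <- function(r0_base, r0_new, tol = 1e-6) {
  d <- r0_new - r0_base
  if (abs(d) < tol) "near-zero" else if (d > 0) "increase" else "decrease"
}

.scenario_registry <- function() {
  list(
    fear_potentiated = list(
      axis = "p_blow", expected = "increase",
      paradigm = "fear-potentiated startle: probe during CS+ vs during CS-",
      defaults = list(assoc_cs_plus = 0.6, assoc_cs_minus = 0.05,
                      p_s_given_b = 1, p_s = 0.96),
      fn = function(p) {
        post <- function(assoc)
          posterior_with_probe(forward_model(p$p_s_given_b, p$p_s,
                                             p_b_given_cs = assoc))$p_blow
        p_minus <- post(p$assoc_cs_minus)
        p_plus <- post(p$assoc_cs_plus)
        r0_minus <- .r0_at(p_minus)
        r0_plus <- .r0_at(p_plus)
        list(computed = .direction(r0_minus, r0_plus),
             detail = data.frame(arm = c("CS-", "CS+"),
                                 p_post = c(p_minus, p_plus),
                                 r0 = c(r0_minus, r0_plus)))
      }),
    cs_alone = list(
      axis = "p_blow", expected = "near-zero",
      paradigm = "CS+ presented without the startle probe elicits no startle",
      defaults = list(assoc_cs_plus = 0.9, p_s_given_b = 1, p_s = 0.96,
                      p_nos_given_b = 0, epsilon = 1e-3),
      fn = function(p) {
        fm <- forward_model(p$p_s_given_b, p$p_s,
                            p_b_given_cs = p$assoc_cs_plus)
        p_post <- posterior_without_probe(fm, p$p_nos_given_b)$p_blow
        r0 <- .r0_at(p_post)
        list(computed = if (p_post < p$epsilon && r0 < 1e-6) "near-zero"
                        else "increase",
             detail = data.frame(arm = "CS+ alone", p_post = p_post, r0 = r0))
      }),
    context_prior = list(
      axis = "prior", expected = "increase",
      paradigm = paste("raised context prior P(B): trace/contextual fear",
                       "conditioning, prior shock exposure, instructed fear,",
                       "species-inappropriate lighting"),
      defaults = list(prior_low = 0.05, prior_high = 0.2,
                      p_s_given_b = 1, p_s = 0.96),
      fn = function(p) {
        post <- function(prior)
          posterior_context_only(forward_model(p$p_s_given_b, p$p_s,
                                               p_b_prior = prior))$p_blow
        r0_low <- .r0_at(post(p$prior_low))
        r0_high <- .r0_at(post(p$prior_high))
        list(computed = .direction(r0_low, r0_high),
             detail = data.frame(arm = c("baseline", "raised prior"),
                                 prior = c(p$prior_low, p$prior_high),
                                 r0 = c(r0_low, r0_high)))
      }),
    reward_anticipation = list(
      axis = "eta", expected = "increase",
      paradigm = "reward anticipation raises opportunity cost at fixed danger",
      defaults = list(p_blow = 0.3, eta_low = 1, eta_high = 2),
      fn = function(p) {
        r0_low <- .r0_at(p$p_blow, eta = p$eta_low)
        r0_high <- .r0_at(p$p_blow, eta = p$eta_high)
        list(computed = .direction(r0_low, r0_high),
             detail = data.frame(arm = c("baseline", "reward anticipated"),
                                 eta = c(p$eta_low, p$eta_high),
                                 r0 = c(r0_low, r0_high)))
      }),
    instructed_attention = list(
      axis = "eta", expected = "increase",
      paradigm = "instructed attention: missing the attended stimulus is costly",
      defaults = list(p_blow = 0.2, eta_low = 1, eta_high = 1.8),
      fn = function(p) {
        r0_low <- .r0_at(p$p_blow, eta = p$eta_low)
        r0_high <- .r0_at(p$p_blow, eta = p$eta_high)
        list(computed = .direction(r0_low, r0_high),
             detail = data.frame(arm = c("unattended", "attended"),
                                 eta = c(p$eta_low, p$eta_high),
                                 r0 = c(r0_low, r0_high)))
      }),
    positive_picture = list(
      axis = "prior", expected = "decrease",
      paradigm = "positively valenced picture viewing lowers the blow prior",
      defaults = list(prior_base = 0.15, prior_positive = 0.05,
                      p_s_given_b = 1, p_s = 0.96),
      fn = function(p) {
        post <- function(prior)
          posterior_context_only(forward_model(p$p_s_given_b, p$p_s,
                                               p_b_prior = prior))$p_blow
        r0_base <- .r0_at(post(p$prior_base))
        r0_pos <- .r0_at(post(p$prior_positive))
        list(computed = .direction(r0_base, r0_pos),
             detail = data.frame(arm = c("neutral", "positive pictures"),
                                 prior = c(p$prior_base, p$prior_positive),
                                 r0 = c(r0_base, r0_pos)))
      }),
    food_deprivation = list(
      axis = "prior+eta", expected = "dissociation",
      paradigm = paste("food stimuli: satiated subjects get only the lowered",
                       "prior (startle down); deprived subjects also get a",
                       "dominant opportunity-cost rise (startle up)"),
      defaults = list(prior_base = 0.1, prior_food = 0.06,
                      eta_deprived = 3, p_s_given_b = 1, p_s = 0.96),
      fn = function(p) {
        post <- function(prior)
          posterior_context_only(forward_model(p$p_s_given_b, p$p_s,
                                               p_b_prior = prior))$p_blow
        r0_base <- .r0_at(post(p$prior_base))
        r0_sat <- .r0_at(post(p$prior_food))
        r0_dep <- .r0_at(post(p$prior_food), eta = p$eta_deprived)
        dir_sat <- .direction(r0_base, r0_sat)
        dir_dep <- .direction(r0_base, r0_dep)
        list(computed = if (dir_sat == "decrease" && dir_dep == "increase")
                          "dissociation" else paste(dir_sat, dir_dep, sep = "/"),
             detail = data.frame(
               arm = c("baseline", "satiated", "deprived"),
               prior = c(p$prior_base, p$prior_food, p$prior_food),
               eta = c(1, 1, p$eta_deprived),
               r0 = c(r0_base, r0_sat, r0_dep)))
      }),
    reward_with_safety = list(
      axis = "prior+eta", expected = "ambiguous",
      paradigm = paste("positive-valence anticipation lowering the prior while",
                       "raising opportunity cost: net direction depends on",
                       "which effect dominates, so no verdict is assigned"),
      defaults = list(prior_base = 0.1, prior_new = 0.05,
                      eta_new = 2, p_s_given_b = 1, p_s = 0.96),
      fn = function(p) {
        post <- function(prior)
          posterior_context_only(forward_model(p$p_s_given_b, p$p_s,
                                               p_b_prior = prior))$p_blow
        r0_base <- .r0_at(post(p$prior_base))
        r0_new <- .r0_at(post(p$prior_new), eta = p$eta_new)
        list(computed = .direction(r0_base, r0_new),
             detail = data.frame(arm = c("baseline", "reward+safety"),
                                 prior = c(p$prior_base, p$prior_new),
                                 eta = c(1, p$eta_new),
                                 r0 = c(r0_base, r0_new)))
      }),
    davis_astrachan = list(
      axis = "us_magnitude", expected = "dissociation",
      paradigm = paste("medium vs high footshock US: monotone extinction",
                       "decline vs rise-then-fall under expectation coding"),
      defaults = list(medium_b = 1.2, high_b = 3, n_acquisition = 10,
                      n_extinction = 30, seed = 1L),
      fn = function(p) {
        dav <- davis_astrachan_scenario(
          medium_b = p$medium_b, high_b = p$high_b,
          n_acquisition = p$n_acquisition, n_extinction = p$n_extinction,
          seed = p$seed)
        sh <- dav$shapes
        get_shape <- function(g, c)
          sh$shape[sh$group == g & sh$coding == c]
        ok <- get_shape("medium", "expectation") == "monotone-decreasing" &&
          get_shape("high", "expectation") == "rise-then-fall"
        list(computed = if (ok) "dissociation"
                        else paste(sh$shape, collapse = "/"),
             detail = sh, extra = dav)
      }))
}

#' Catalogue of shipped qualitative-prediction scenarios
#'
#' One row per registered scenario: the manipulation axis, the paradigm it
#' emulates, and the qualitative direction of the optimal-startle change the
#' model predicts (`"ambiguous"` scenarios are reported descriptively and
#' never given a pass/fail verdict).
#'
#' @return A data frame with columns `scenario`, `axis`, `expected`,
#'   `paradigm`.
#' @export
scenario_catalog <- function() {
  reg <- .scenario_registry()
  data.frame(scenario = names(reg),
             axis = vapply(reg, `[[`, "", "axis"),
             expected = vapply(reg, `[[`, "", "expected"),
             paradigm = vapply(reg, `[[`, "", "paradigm"),
             row.names = NULL)
}

#' Run a single shipped scenario
#'
#' Executes the underlying model components for the named scenario,
#' classifies the direction of the optimal-startle change along its
#' manipulation axis, and compares it with the expected label. For
#' `"ambiguous"` scenarios the computed direction is reported and `pass` is
#' `NA`.
#'
#' @param name Registered scenario name (see [scenario_catalog()]).
#' @param overrides Named list overriding the scenario's default parameters;
#'   unknown keys are an error.
#' @param out_dir If non-`NULL`, per-arm results are written there as CSV
#'   (plus trajectory CSVs for the conditioning scenario).
#' @param seed Integer seed (scenarios are deterministic; the seed is
#'   forwarded to protocol-based scenarios and recorded).
#' @return A one-row data frame (`scenario`, `axis`, `expected`, `computed`,
#'   `pass`) with the per-arm detail attached as attribute `"detail"`.
#' @examples
#' run_scenario("fear_potentiated")
#' @export
run_scenario <- function(name, overrides = list(), out_dir = NULL, seed = 1L) {
  reg <- .scenario_registry()
  sc <- reg[[name]]
  if (is.null(sc))
    stop(sprintf("unknown scenario '%s'; see scenario_catalog()", name))
  unknown <- setdiff(names(overrides), names(sc$defaults))
  if (length(unknown))
    stop(sprintf("override key(s) not in scenario schema: %s",
                 paste(unknown, collapse = ", ")))
  params <- utils::modifyList(sc$defaults, overrides)
  if ("seed" %in% names(sc$defaults) && !"seed" %in% names(overrides))
    params$seed <- as.integer(seed)
  res <- sc$fn(params)
  pass <- if (sc$expected == "ambiguous") NA else
    identical(res$computed, sc$expected)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$detail,
                     file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    if (!is.null(res$extra) && inherits(res$extra, "davis_astrachan")) {
      write_trajectory(res$extra$medium,
                       file.path(out_dir, paste0(name, "_medium.csv")))
      write_trajectory(res$extra$high,
                       file.path(out_dir, paste0(name, "_high.csv")))
    }
  }
  out <- data.frame(scenario = name, axis = sc$axis, expected = sc$expected,
                    computed = res$computed, pass = pass)
  attr(out, "detail") <- res$detail
  out
}

#' Run every registered scenario and assemble a prediction report
#'
#' @param report_path If non-`NULL`, the report is also written there as
#'   JSON.
#' @param out_dir Optional artefact directory forwarded to [run_scenario()].
#' @param seed Seed forwarded to each scenario.
#' @return A data frame of class `prediction_report`, one row per scenario,
#'   with columns as in [run_scenario()]. Rerunning with the same seed gives
#'   an identical report.
#' @export
run_all_scenarios <- function(report_path = NULL, out_dir = NULL, seed = 1L) {
  rows <- lapply(names(.scenario_registry()), run_scenario,
                 out_dir = out_dir, seed = seed)
  report <- do.call(rbind, rows)
  class(report) <- c("prediction_report", "data.frame")
  if (!is.null(report_path)) {
    dir.create(dirname(report_path), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, report_path, dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  }
  report
}

#' @export
print.prediction_report <- function(x, ...) {
  n_det <- sum(!is.na(x$pass))
  cat(sprintf("<prediction_report> %d scenarios (%d determinate, %d passing)\n",
              nrow(x), n_det, sum(x$pass, na.rm = TRUE)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
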