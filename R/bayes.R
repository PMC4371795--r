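#' Forward model of startle-probe and blow contingencies
#'
#' Bundles the scenario constants from which the blow probability
#' \eqn{P(B|X)} is computed by Bayes' rule:
#'
#' * `p_s_given_b`: \eqn{P(S|B)}, probability of the startle probe given an
#'   immediate blow (close to 1: a blow is almost always preceded by a sudden
#'   stimulus);
#' * `p_s`: \eqn{P(S)}, marginal probability of the probe;
#' * `p_b_given_cs`: \eqn{P(B|CS)}, the learned association between the
#'   currently presented conditioned stimulus and the blow (for a CS− this is
#'   the CS− value);
#' * `p_b_prior`: \eqn{P(B)}, the context prior used when no CS is present.
#'
#' These are treated as scenario constants, not learned from data.
#'
#' @param p_s_given_b,p_s,p_b_given_cs,p_b_prior Probabilities; `p_s` must be
#'   strictly positive.
#' @return An object of class `forward_model`.
#' @seealso [posterior_with_probe()], [posterior_without_probe()],
#'   [posterior_context_only()]
#' @export
forward_model <- function(p_s_given_b = 1, p_s = 0.96, p_b_given_cs = 0,
                          p_b_prior = 0.05) {
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("`%s` must be a single probability in [0, 1]", nm))
  }
  chk(p_s_given_b, "p_s_given_b"); chk(p_s, "p_s")
  chk(p_b_given_cs, "p_b_given_cs"); chk(p_b_prior, "p_b_prior")
  if (p_s <= 0) stop("`p_s` must be strictly positive")
  structure(list(p_s_given_b = p_s_given_b, p_s = p_s,
                 p_b_given_cs = p_b_given_cs, p_b_prior = p_b_prior),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(paste0("<forward_model> P(S|B) = %g, P(S) = %g, ",
                     "P(B|CS) = %g, P(B) = %g\n"),
              x$p_s_given_b, x$p_s, x$p_b_given_cs, x$p_b_prior))
  invisible(x)
}

# The Bayes expressions are likelihood-ratio-scaled priors under the
# independence simplification p(S, CS) = p(S) p(CS); for extreme parameter
# combinations they can exceed 1. We clamp to [0, 1] with a warning rather
# than silently altering the formula in its valid regime; shipped scenarios
# never trigger the clamp (asserted in the test suite).
.clamp_posterior <- function(p) {
  if (p > 1) {
    warning(sprintf("posterior %.4g exceeds 1; clamped (forward model outside its valid regime)", p))
    p <- 1
  }
  blow_belief(min(1, max(0, p)))
}

#' Blow probability when the startle probe occurs during a CS
#'
#' Computes \eqn{P(B | X = \{S, CS\}) = P(S|B) P(B|CS) / P(S)}, the
#' posterior blow probability when the probe is presented during the
#' conditioned stimulus. Fear conditioning changes `p_b_given_cs`, and this
#' posterior is monotonically increasing in it — which, combined with the
#' blow-probability monotonicity of [optimal_startle()], yields
#' fear-potentiated startle: a larger startle to the probe during a CS+ than
#' during a CS−.
#'
#' @param fm A [forward_model()].
#' @return A [blow_belief()].
#' @examples
#' posterior_with_probe(forward_model(1, 0.5, p_b_given_cs = 0.3))  # 0.6
#' @export
posterior_with_probe <- function(fm) {
  stopifnot(inherits(fm, "forward_model"))
  .clamp_posterior(fm$p_s_given_b * fm$p_b_given_cs / fm$p_s)
}

#' Blow probability when the CS is presented without the probe
#'
#' Computes \eqn{P(B | X = \{\neg S, CS\}) = P(\neg S|B) P(B|CS) / P(\neg S)}.
#' Because a blow is almost never unheralded, \eqn{P(\neg S|B) \approx 0} and
#' the posterior is near zero: animals should not startle to a CS presented
#' on its own, however strong the learned association.
#'
#' @param fm A [forward_model()].
#' @param p_nos_given_b \eqn{P(\neg S|B)} in `[0, 1]`.
#' @return A [blow_belief()]; exactly 0 when `p_nos_given_b` is 0.
#' @examples
#' posterior_without_probe(forward_model(p_s = 0.5, p_b_given_cs = 0.5), 0.01)
#' @export
posterior_without_probe <- function(fm, p_nos_given_b) {
  stopifnot(inherits(fm, "forward_model"))
  if (!is.numeric(p_nos_given_b) || length(p_nos_given_b) != 1L ||
      !is.finite(p_nos_given_b) || p_nos_given_b < 0 || p_nos_given_b > 1)
    stop("`p_nos_given_b` must be a single probability in [0, 1]")
  p_nos <- 1 - fm$p_s
  if (p_nos <= 0)
    stop("P(S) = 1 leaves no probe-free trials: P(not S) must be positive")
  .clamp_posterior(p_nos_given_b * fm$p_b_given_cs / p_nos)
}

#' Blow probability from the context prior alone
#'
#' Computes \eqn{P(B | X = S) = P(S|B) P(B) / P(S)} — the probe posterior
#' driven only by the context prior \eqn{P(B)}, which does not depend on the
#' sensory input at probe time and is estimated from past experience. Raising
#' the prior (contextual or trace fear conditioning, prior shock exposure,
#' instructed fear, species-inappropriate lighting) raises this posterior and
#' therefore the optimal startle magnitude.
#'
#' @param fm A [forward_model()].
#' @return A [blow_belief()].
#' @examples
#' posterior_context_only(forward_model(1, 0.5, p_b_prior = 0.1))  # 0.2
#' @export
posterior_context_only <- function(fm) {
  stopifnot(inherits(fm, "forward_model"))
  .clamp_posterior(fm$p_s_given_b * fm$p_b_prior / fm$p_s)
}
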