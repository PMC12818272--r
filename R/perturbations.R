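#' Perturbation rule mapping true risks to predictions
#'
#' Describes how predicted probabilities are derived from the true
#' probabilities in a simulation scenario: identical to the truth
#' (`identity`), shifted by a constant (`additive_bias`), jittered with
#' independent uniform noise (`uniform_noise`), or jittered with symmetric
#' Gaussian noise on the log-odds scale (`logit_noise`).
#'
#' `magnitude` is the bias for `additive_bias`, the half-width `m` of the
#' `Unif(-m, m)` noise for `uniform_noise`, and the standard deviation of
#' the log-odds error for `logit_noise`. It must be 0 for `identity`, and a
#' zero magnitude makes every kind the identity.
#'
#' Out-of-range predictions are handled per `clip_policy`: `"clip_to_unit"`
#' (default) clamps to \[0, 1\]; `"reject"` raises a
#' `briersim_reject_error` so the affected replicate aborts. Degenerate
#' risks `q_i` of 0 or 1 are fixed points of `logit_noise` (their log-odds
#' are infinite).
#'
#' @param kind one of `"identity"`, `"additive_bias"`, `"uniform_noise"`,
#'   `"logit_noise"`.
#' @param magnitude non-negative scalar, see Details.
#' @param clip_policy `"clip_to_unit"` or `"reject"`.
#' @return An object of class `perturbation_spec`.
#' @examples
#' perturbation_spec("uniform_noise", 0.1)
#' @export
perturbation_spec <- function(kind = c("identity", "additive_bias",
                                       "uniform_noise", "logit_noise"),
                              magnitude = 0,
                              clip_policy = c("clip_to_unit", "reject")) {
  kind <- match.arg(kind)
  clip_policy <- match.arg(clip_policy)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || is.na(magnitude) ||
      magnitude < 0) {
    stop_validation("`magnitude` must be a single non-negative number")
  }
  if (kind == "identity" && magnitude != 0) {
    stop_validation("identity perturbation requires magnitude 0")
  }
  structure(list(kind = kind, magnitude = as.numeric(magnitude),
                 clip_policy = clip_policy),
            class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf("<perturbation_spec> %s (magnitude = %g, %s)\n",
              x$kind, x$magnitude, x$clip_policy))
  invisible(x)
}

#' Apply a perturbation rule to true probabilities
#'
#' Produces the predicted probabilities `p` from the true probabilities `q`
#' under a [perturbation_spec()]. Stochastic rules draw from the stream
#' seeded by `seed`; with `seed = NULL` the current RNG stream is consumed,
#' which is how the simulation engine threads its per-replicate child
#' seeds.
#'
#' For interior `q` the expected Brier score of the perturbed predictions
#' exceeds the perfect expectation by exactly `magnitude^2` under
#' `additive_bias` and by `magnitude^2 / 3` in expectation under
#' `uniform_noise` (the second moment of `Unif(-m, m)`).
#'
#' @param q a [truth_model()] or numeric probability vector.
#' @param spec a [perturbation_spec()].
#' @param seed integer seed or NULL.
#' @return Numeric vector of predictions in \[0, 1\], same length as `q`.
#' @examples
#' apply_perturbation(c(0.3, 0.7), perturbation_spec("additive_bias", 0.1))
#' @export
apply_perturbation <- function(q, spec, seed = NULL) {
  q <- as_truth(q)$q
  if (!inherits(spec, "perturbation_spec")) {
    stop_validation("`spec` must be a perturbation_spec")
  }
  m <- spec$magnitude
  p <- with_seed(seed, switch(
    spec$kind,
    identity = q,
    additive_bias = q + m,
    uniform_noise = if (m == 0) q else q + stats::runif(length(q), -m, m),
    logit_noise = if (m == 0) q else {
      expit(logit(q) + stats::rnorm(length(q), 0, m))
    }
  ))
  apply_clip_policy(p, spec$clip_policy)
}

apply_clip_policy <- function(p, clip_policy) {
  out <- p < 0 | p > 1
  if (!any(out)) return(p)
  if (clip_policy == "reject") {
    stop_briersim(
      sprintf("%d perturbed prediction(s) left [0, 1] under the reject policy",
              sum(out)),
      "briersim_reject_error")
  }
  pmin(pmax(p, 0), 1)
}
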