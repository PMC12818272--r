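#' Observed Brier score
#'
#' The mean squared difference between predicted probabilities and observed
#' binary outcomes,
#' \deqn{BS(p, y) = \frac{1}{n}\sum_{i=1}^n (p_i - y_i)^2,}
#' ranging over \[0, 1\] with lower values better. Because the outcomes are
#' realisations of Bernoulli random variables, the observed score is itself
#' a realisation of a random variable; see [expected_brier()] for its
#' expectation under known true risks.
#'
#' @param ps a [prediction_set()].
#' @return A [metric_value()] named `"brier_score"`.
#' @examples
#' brier_score(prediction_set(c(0.2, 0.8, 0.5, 0.5), c(0, 1, 1, 0)))
#' @export
brier_score <- function(ps) {
  if (!inherits(ps, "prediction_set")) stop_validation("`ps` must be a prediction_set")
  metric_value("brier_score", mean((ps$p - ps$y)^2), ps$n)
}

#' Expected Brier score under known true risks
#'
#' For outcomes `Y_i ~ Bern(q_i)` the expectation of the Brier score of
#' predictions `p` decomposes exactly as
#' \deqn{E[BS] = \frac{1}{n}\sum_i \left[(p_i - q_i)^2 + q_i(1 - q_i)\right],}
#' the squared distance of the predictions from the truth plus the
#' irreducible Bernoulli variance. The score is strictly proper: the
#' expectation is uniquely minimised at `p = q`, where it equals
#' [perfect_expected_brier()].
#'
#' @param p numeric vector of predicted probabilities.
#' @param q a [truth_model()] or numeric vector of true probabilities,
#'   same length as `p`.
#' @return A [metric_value()] named `"expected_brier"`.
#' @examples
#' expected_brier(0, 0.1)      # 0.1
#' expected_brier(0.25, 0.1)   # 0.1125
#' expected_brier(c(0.3, 0.7), c(0.3, 0.7))  # 0.21, the perfect expectation
#' @export
expected_brier <- function(p, q) {
  q <- as_truth(q)
  p <- check_probability(p, "p")
  check_same_length(p, q$q, "`p` and `q`")
  metric_value("expected_brier",
               mean((p - q$q)^2 + q$q * (1 - q$q)), q$n)
}

#' Expected Brier score of perfect predictions
#'
#' The minimum attainable expected Brier score, reached when every
#' prediction equals the true risk: `(1/n) sum q_i (1 - q_i)`. It is zero
#' only when every `q_i` is 0 or 1; for interior risks even a perfect model
#' scores above zero — e.g. 0.25 when all `q_i = 1/2`.
#'
#' @param q a [truth_model()] or numeric probability vector.
#' @return A [metric_value()] named `"perfect_expected_brier"`.
#' @examples
#' perfect_expected_brier(rep(0.5, 10))  # 0.25
#' perfect_expected_brier(c(0, 1, 1))    # 0
#' @export
perfect_expected_brier <- function(q) {
  q <- as_truth(q)
  metric_value("perfect_expected_brier", mean(q$q * (1 - q$q)), q$n)
}

#' Prevalence reference score
#'
#' `ybar - ybar^2`, where `ybar` is the observed incidence: algebraically
#' the Brier score of the constant prediction `p_i = ybar`, and hence a
#' non-informative baseline. A model score near this value does not by
#' itself imply a useless model — perfect predictions approach it whenever
#' the true risks cluster around the incidence.
#'
#' @param y binary outcome vector (0/1).
#' @return A [metric_value()] named `"prevalence_reference"`.
#' @examples
#' prevalence_reference(rep(c(0, 1), 5))        # ybar 0.5 -> 0.25
#' prevalence_reference(c(rep(0, 9), 1))        # ybar 0.1 -> 0.09
#' @export
prevalence_reference <- function(y) {
  y <- check_binary(y)
  ybar <- mean(y)
  metric_value("prevalence_reference", ybar - ybar^2, length(y))
}

#' Theoretical upper reference for the perfect expectation
#'
#' `qbar - qbar^2` with `qbar` the mean true risk. By Jensen's inequality
#' this bounds [perfect_expected_brier()] from above, with equality exactly
#' when all `q_i` coincide; it is the "blue bar" annotation used alongside
#' simulated score distributions.
#'
#' @param q a [truth_model()] or numeric probability vector.
#' @return A [metric_value()] named `"truth_reference"`.
#' @examples
#' truth_reference(c(0.2, 0.8))  # 0.25, above perfect expectation 0.16
#' @export
truth_reference <- function(q) {
  q <- as_truth(q)
  qbar <- mean(q$q)
  metric_value("truth_reference", qbar - qbar^2, q$n)
}

#' Calibration-in-the-large
#'
#' The difference between the mean predicted probability and the observed
#' event rate, `mean(p) - mean(y)`. Zero indicates agreement in the large;
#' positive values indicate systematic overestimation. A low Brier score
#' does not imply good calibration — symmetric errors of either sign are
#' penalised identically by the Brier score but move CIL in opposite
#' directions.
#'
#' @param ps a [prediction_set()].
#' @return A [metric_value()] named `"cil"`.
#' @examples
#' calibration_in_the_large(prediction_set(c(0.4, 0.6), c(0, 1)))
#' @export
calibration_in_the_large <- function(ps) {
  if (!inherits(ps, "prediction_set")) stop_validation("`ps` must be a prediction_set")
  metric_value("cil", mean(ps$p) - mean(ps$y), ps$n)
}

#' Expected calibration-in-the-large
#'
#' Expectation of [calibration_in_the_large()] over outcomes
#' `Y_i ~ Bern(q_i)`: since `E[mean(y)] = mean(q)`, this is
#' `mean(p) - mean(q)`.
#'
#' @param p numeric vector of predicted probabilities.
#' @param q a [truth_model()] or numeric vector, same length as `p`.
#' @return A [metric_value()] named `"expected_cil"`.
#' @examples
#' expected_cil(c(0.444949, 1), c(0.2, 0.8))  # 0.2224745
#' @export
expected_cil <- function(p, q) {
  q <- as_truth(q)
  p <- check_probability(p, "p")
  check_same_length(p, q$q, "`p` and `q`")
  metric_value("expected_cil", mean(p) - mean(q$q), q$n)
}

#' Scaled Brier score
#'
#' `1 - BS / (ybar (1 - ybar))`: the Brier score rescaled against the
#' prevalence baseline. 0 means no better than the constant-incidence
#' prediction (whose Brier score is exactly `ybar - ybar^2`), 1 means a
#' perfect extreme fit. Undefined when `ybar` is 0 or 1 (zero baseline); a
#' `briersim_undefined_reference` error is raised rather than returning an
#' infinity. Like the raw score, it depends on the underlying risk
#' distribution, so cross-population comparisons remain inadvisable.
#'
#' @param ps a [prediction_set()] with `mean(y)` strictly inside (0, 1).
#' @return A [metric_value()] named `"scaled_brier"`.
#' @examples
#' scaled_brier(prediction_set(c(0.2, 0.8, 0.5, 0.5), c(0, 1, 1, 0)))  # 0.42
#' @export
scaled_brier <- function(ps) {
  if (!inherits(ps, "prediction_set")) stop_validation("`ps` must be a prediction_set")
  ybar <- mean(ps$y)
  if (ybar %in% c(0, 1)) {
    stop_briersim(
      "scaled Brier score is undefined when all outcomes are identical (ybar in {0, 1})",
      "briersim_undefined_reference")
  }
  bs <- brier_score(ps)$value
  metric_value("scaled_brier", 1 - bs / (ybar * (1 - ybar)), ps$n)
}

#' Euclidean distance between probability vectors
#'
#' `sqrt(sum((p - q)^2))`. The expected Brier score preserves the ordering
#' induced by this distance to the true probabilities: predictions closer
#' to `q` in l2 have lower expected score. The squared distance divided by
#' `n` is exactly the excess of [expected_brier()] over
#' [perfect_expected_brier()].
#'
#' @param p,q numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @examples
#' l2_distance(c(0.25), c(0.1))  # 0.15
#' @export
l2_distance <- function(p, q) {
  if (inherits(q, "truth_model")) q <- q$q
  if (!is.numeric(p) || !is.numeric(q)) stop_validation("`p` and `q` must be numeric")
  check_same_length(p, q, "`p` and `q`")
  sqrt(sum((p - q)^2))
}
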