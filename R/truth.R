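#' Truth-distribution specification
#'
#' Describes the data-generating mechanism for the true event probabilities
#' `q` in a simulation scenario. Supported families:
#'
#' * `constant`: all `q_i = value`.
#' * `uniform`: `q_i ~ Unif(min, max)` with `0 <= min < max <= 1`.
#' * `beta`: `q_i ~ Beta(shape1, shape2)`.
#' * `two_point`: `q_i = v1` with probability `w`, else `v0` (the classical
#'   0/1-with-equal-weight case is the default).
#' * `logistic_model`: `q_i = expit(intercept + x_i' beta)` with covariates
#'   `x_i` drawn i.i.d. from a standard normal — an emulation of risks
#'   produced by a fitted logistic regression, as in survey-based
#'   prediction models. See [nhanes_like_spec()] for solving the intercept
#'   to hit a target prevalence.
#'
#' @param family one of `"constant"`, `"uniform"`, `"beta"`, `"two_point"`,
#'   `"logistic_model"`.
#' @param n sample size (number of probabilities to draw).
#' @param ... family-specific parameters: `value` (constant); `min`, `max`
#'   (uniform); `shape1`, `shape2` (beta); `v0`, `v1`, `w` (two_point);
#'   `beta`, `intercept`, `covariates` (logistic_model; `covariates` is
#'   currently only `"std_normal"`).
#' @return An object of class `truth_spec`.
#' @examples
#' truth_spec("beta", n = 300, shape1 = 1, shape2 = 3)
#' truth_spec("two_point", n = 100)
#' @export
truth_spec <- function(family = c("constant", "uniform", "beta", "two_point",
                                  "logistic_model"),
                       n, ...) {
  family <- match.arg(family)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop_validation("`n` must be a positive integer")
  }
  n <- as.integer(n)
  params <- list(...)
  params <- switch(
    family,
    constant = {
      value <- params$value %||% 0.5
      check_probability(value, "value")
      list(value = as.numeric(value))
    },
    uniform = {
      min <- params$min %||% 0
      max <- params$max %||% 1
      if (!(min >= 0 && min < max && max <= 1)) {
        stop_validation("uniform family requires 0 <= min < max <= 1")
      }
      list(min = as.numeric(min), max = as.numeric(max))
    },
    beta = {
      shape1 <- params$shape1 %||% 1
      shape2 <- params$shape2 %||% 1
      if (shape1 <= 0 || shape2 <= 0) {
        stop_validation("beta family requires positive shape parameters")
      }
      list(shape1 = as.numeric(shape1), shape2 = as.numeric(shape2))
    },
    two_point = {
      v0 <- params$v0 %||% 0
      v1 <- params$v1 %||% 1
      w <- params$w %||% 0.5
      check_probability(v0, "v0"); check_probability(v1, "v1")
      check_probability(w, "w")
      list(v0 = as.numeric(v0), v1 = as.numeric(v1), w = as.numeric(w))
    },
    logistic_model = {
      beta <- params$beta %||% stop_validation("logistic_model requires `beta`")
      intercept <- params$intercept %||% 0
      if (!is.numeric(beta) || length(beta) < 1L || anyNA(beta)) {
        stop_validation("`beta` must be a numeric coefficient vector")
      }
      covariates <- params$covariates %||% "std_normal"
      if (!identical(covariates, "std_normal")) {
        stop_validation("only the std_normal covariate law is implemented")
      }
      list(beta = as.numeric(beta), intercept = as.numeric(intercept),
           k = length(beta), covariates = covariates)
    }
  )
  structure(list(family = family, params = params, n = n),
            class = "truth_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.truth_spec <- function(x, ...) {
  pstr <- paste(names(x$params),
                vapply(x$params, function(v) paste(format(v), collapse = ","),
                       character(1)),
                sep = "=", collapse = ", ")
  cat(sprintf("<truth_spec> %s(%s), n = %d\n", x$family, pstr, x$n))
  invisible(x)
}

#' Sample true event probabilities
#'
#' Draws a vector of true probabilities from a [truth_spec()]. A fixed seed
#' yields bit-identical output across runs.
#'
#' @param spec a [truth_spec()].
#' @param seed integer seed or NULL (use the current RNG stream).
#' @return A [truth_model()] of length `spec$n`.
#' @examples
#' sample_true_probabilities(truth_spec("uniform", n = 5), seed = 1)
#' @export
sample_true_probabilities <- function(spec, seed = NULL) {
  if (!inherits(spec, "truth_spec")) stop_validation("`spec` must be a truth_spec")
  n <- spec$n
  pr <- spec$params
  q <- with_seed(seed, switch(
    spec$family,
    constant = rep(pr$value, n),
    uniform = stats::runif(n, pr$min, pr$max),
    beta = stats::rbeta(n, pr$shape1, pr$shape2),
    two_point = ifelse(stats::runif(n) < pr$w, pr$v1, pr$v0),
    logistic_model = {
      x <- matrix(stats::rnorm(n * pr$k), nrow = n, ncol = pr$k)
      expit(pr$intercept + drop(x %*% pr$beta))
    }
  ))
  truth_model(q, source = spec$family)
}

#' Sample Bernoulli outcomes under true risks
#'
#' `Y_i ~ Bern(q_i)`, independently. Deterministic given the seed.
#'
#' @param q a [truth_model()] or numeric probability vector.
#' @param seed integer seed or NULL.
#' @return Numeric 0/1 vector of the same length as `q`.
#' @examples
#' sample_outcomes(c(0.2, 0.8, 0.5), seed = 1)
#' @export
sample_outcomes <- function(q, seed = NULL) {
  q <- as_truth(q)$q
  with_seed(seed, stats::rbinom(length(q), 1L, q)) * 1.0
}

#' Logistic truth model calibrated to a target prevalence
#'
#' Builds a `logistic_model` [truth_spec()] with `k` standard-normal
#' covariates and coefficients `beta`, solving the intercept numerically so
#' that the induced distribution of `q = expit(intercept + x' beta)` has
#' mean `prevalence_target`. This emulates risks obtained from a fitted
#' logistic regression on survey data without requiring any real data: only
#' the mechanism (logistic risks with a set prevalence), not specific
#' fitted values, is reproduced.
#'
#' Because `x' beta ~ N(0, s^2)` with `s^2 = sum(beta^2)`, the mean risk is
#' `E[expit(b0 + s Z)]`, computed by Gaussian quadrature ([stats::integrate()])
#' and inverted with [stats::uniroot()]. The achieved prevalence is then
#' verified on a seeded Monte-Carlo draw; a discrepancy above 0.01 raises a
#' `briersim_convergence_error`.
#'
#' @param prevalence_target target mean of `q`, strictly inside (0, 1).
#' @param k number of covariates (`>= 1`).
#' @param beta coefficient vector of length `k`; default `rep(0.5, k)`.
#' @param n sample size recorded in the returned spec.
#' @param seed seed for the Monte-Carlo verification draw.
#' @param check_n size of the verification draw.
#' @return A [truth_spec()] with family `logistic_model`.
#' @examples
#' sp <- nhanes_like_spec(0.2, k = 3, n = 300, seed = 1)
#' mean(sample_true_probabilities(sp, seed = 2)$q)
#' @export
nhanes_like_spec <- function(prevalence_target, k = 3L, beta = rep(0.5, k),
                             n = 1000L, seed = NULL, check_n = 100000L) {
  if (!is.numeric(prevalence_target) || length(prevalence_target) != 1L ||
      is.na(prevalence_target) || prevalence_target <= 0 ||
      prevalence_target >= 1) {
    stop_validation("`prevalence_target` must lie strictly inside (0, 1)")
  }
  if (k < 1L || length(beta) != k) {
    stop_validation("`k` must be >= 1 and `beta` must have length k")
  }
  s <- sqrt(sum(beta^2))
  if (s == 0) {
    b0 <- logit(prevalence_target)
  } else {
    mean_risk <- function(b0) {
      stats::integrate(function(z) expit(b0 + s * z) * stats::dnorm(z),
                       lower = -10, upper = 10, rel.tol = 1e-10)$value
    }
    sol <- tryCatch(
      stats::uniroot(function(b0) mean_risk(b0) - prevalence_target,
                     interval = c(-50, 50), tol = 1e-10),
      error = function(e) stop_briersim(
        sprintf("intercept solve failed: %s", conditionMessage(e)),
        "briersim_convergence_error"))
    b0 <- sol$root
  }
  spec <- truth_spec("logistic_model", n = n, beta = beta, intercept = b0)
  achieved <- mean(sample_true_probabilities(
    truth_spec("logistic_model", n = check_n, beta = beta, intercept = b0),
    seed = seed)$q)
  if (abs(achieved - prevalence_target) > 0.01) {
    stop_briersim(
      sprintf("achieved prevalence %.4f misses target %.4f by more than 0.01",
              achieved, prevalence_target),
      "briersim_convergence_error")
  }
  spec
}

#' Subsample a pool of true probabilities without replacement
#'
#' Mirrors the mechanism of drawing a scenario's risks from a larger pool
#' of model-based probabilities by sampling without replacement, which
#' preserves the pool's distribution in expectation.
#'
#' @param pool a [truth_model()] or numeric probability vector.
#' @param n number of values to draw (`n <= length(pool)`).
#' @param seed integer seed or NULL.
#' @return A [truth_model()] of length `n`.
#' @export
subsample_truth <- function(pool, n, seed = NULL) {
  pool <- as_truth(pool)
  if (n < 1L || n > pool$n) {
    stop_validation("`n` must be between 1 and the pool size")
  }
  q <- with_seed(seed, sample(pool$q, size = n, replace = FALSE))
  truth_model(q, source = paste0(pool$source, "_subsample"))
}

# E[q] for a truth family: closed form where one exists, Gaussian
# quadrature for the logistic model (x'beta ~ N(0, sum(beta^2))).
truth_mean <- function(spec) {
  pr <- spec$params
  switch(spec$family,
         constant = pr$value,
         uniform = (pr$min + pr$max) / 2,
         beta = pr$shape1 / (pr$shape1 + pr$shape2),
         two_point = pr$w * pr$v1 + (1 - pr$w) * pr$v0,
         logistic_model = logistic_moment(pr, function(q) q))
}

# E[q^2], same conventions as truth_mean().
truth_second_moment <- function(spec) {
  pr <- spec$params
  switch(spec$family,
         constant = pr$value^2,
         uniform = (pr$min^2 + pr$min * pr$max + pr$max^2) / 3,
         beta = {
           a <- pr$shape1; b <- pr$shape2
           a * (a + 1) / ((a + b) * (a + b + 1))
         },
         two_point = pr$w * pr$v1^2 + (1 - pr$w) * pr$v0^2,
         logistic_model = logistic_moment(pr, function(q) q^2))
}

logistic_moment <- function(pr, g) {
  s <- sqrt(sum(pr$beta^2))
  if (s == 0) return(g(expit(pr$intercept)))
  stats::integrate(function(z) g(expit(pr$intercept + s * z)) * stats::dnorm(z),
                   lower = -12, upper = 12, rel.tol = 1e-10)$value
}
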