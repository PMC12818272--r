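#' Simulation scenario specification
#'
#' One cell of the Monte-Carlo study: a truth distribution, a perturbation
#' rule, a sample size, a replicate count and a master seed. Defaults
#' follow the study design the engine reproduces: sample sizes of 300 or
#' 1000 with 5000 replicates per scenario.
#'
#' @param truth a [truth_spec()]; its `n` is overridden by the scenario's
#'   `n`.
#' @param perturbation a [perturbation_spec()]; default identity (perfect
#'   predictions).
#' @param n observations per replicate.
#' @param replicates number of Monte-Carlo replicates (`>= 1`).
#' @param master_seed integer master seed; each replicate runs on a child
#'   seed derived from it (see [run_scenario()]).
#' @param label scenario label used in reports and output file names.
#' @param redraw_q if TRUE (default) the true probabilities are redrawn
#'   i.i.d. in every replicate; if FALSE one `q` vector is drawn once and
#'   held fixed across replicates, as when risks are subsampled from a
#'   fitted-model pool.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec(truth_spec("uniform", n = 300),
#'               perturbation_spec("uniform_noise", 0.1),
#'               n = 300, replicates = 100, master_seed = 1,
#'               label = "uniform_noise_300")
#' @export
scenario_spec <- function(truth,
                          perturbation = perturbation_spec("identity"),
                          n = 300L, replicates = 5000L, master_seed = 1L,
                          label = "scenario", redraw_q = TRUE) {
  if (!inherits(truth, "truth_spec")) stop_validation("`truth` must be a truth_spec")
  if (!inherits(perturbation, "perturbation_spec")) {
    stop_validation("`perturbation` must be a perturbation_spec")
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop_validation("`replicates` must be >= 1")
  }
  if (!is.numeric(n) || n < 1) stop_validation("`n` must be >= 1")
  truth$n <- as.integer(n)
  structure(list(truth = truth, perturbation = perturbation,
                 n = as.integer(n), replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed),
                 label = as.character(label)[1L],
                 redraw_q = isTRUE(redraw_q)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: %s truth, %s perturbation, n = %d, %d replicates, seed %d\n",
              x$label, x$truth$family, x$perturbation$kind, x$n,
              x$replicates, x$master_seed))
  invisible(x)
}

#' Run one Monte-Carlo scenario
#'
#' For each replicate: draw true probabilities `q` (redrawn per replicate
#' by default), draw outcomes `Y_i ~ Bern(q_i)`, derive predictions `p` via
#' the perturbation rule, and record the observed Brier score, the Brier
#' score of the perfect predictions `p = q` on the same outcomes,
#' calibration-in-the-large, the prevalence reference `ybar - ybar^2`, the
#' gap `ybar - ybar^2 - BS_perf`, and the exceedance flag
#' `ybar - ybar^2 > BS` (strict).
#'
#' Reproducibility: `set.seed(master_seed)` spawns one child seed per
#' replicate up front, and every replicate runs on its own child stream, so
#' results are identical for identical specs and independent of execution
#' order. A rejection under the `reject` clip policy aborts with the
#' replicate index attached.
#'
#' @param spec a [scenario_spec()].
#' @return A `replicate_table`: a data frame with one row per replicate and
#'   columns `replicate`, `brier`, `brier_perfect`, `cil`,
#'   `prevalence_reference`, `gap`, `exceed`; the scenario spec is attached
#'   as attribute `"scenario"`.
#' @examples
#' tab <- run_scenario(scenario_spec(truth_spec("constant", n = 50, value = 0.5),
#'                                   n = 50, replicates = 20, master_seed = 7))
#' summary(tab$brier)
#' @export
run_scenario <- function(spec) {
  if (!inherits(spec, "scenario_spec")) stop_validation("`spec` must be a scenario_spec")
  R <- spec$replicates
  seeds <- child_seeds(spec$master_seed, R + 1L)
  fixed_q <- if (!spec$redraw_q) {
    sample_true_probabilities(spec$truth, seed = seeds[R + 1L])
  }
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    rows[[r]] <- with_seed(seeds[r], {
      q <- if (spec$redraw_q) sample_true_probabilities(spec$truth) else fixed_q
      y <- sample_outcomes(q)
      p <- tryCatch(
        apply_perturbation(q, spec$perturbation),
        briersim_reject_error = function(e) {
          stop_briersim(sprintf("replicate %d: %s", r, conditionMessage(e)),
                        "briersim_reject_error")
        })
      bs <- mean((p - y)^2)
      bs_perf <- mean((q$q - y)^2)
      ybar <- mean(y)
      pref <- ybar - ybar^2
      c(brier = bs, brier_perfect = bs_perf,
        cil = mean(p) - ybar, prevalence_reference = pref,
        gap = pref - bs_perf, exceed = as.numeric(pref > bs))
    })
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$exceed <- out$exceed > 0
  out <- cbind(replicate = seq_len(R), out)
  attr(out, "scenario") <- spec
  class(out) <- c("replicate_table", "data.frame")
  out
}

#' Summarise a scenario's replicate table
#'
#' Computes, per recorded metric, the mean, median and 5th/95th percentiles
#' (type-7 linear-interpolation sample quantiles), plus the exceedance
#' probability `P(ybar - ybar^2 > BS)` with a percentile-bootstrap 95%
#' confidence interval obtained by resampling replicates. The theoretical
#' reference `qbar - qbar^2` of the truth distribution (the "blue bar"
#' annotation) and the analytic expected Brier score are attached when the
#' scenario spec is available.
#'
#' @param table a `replicate_table` from [run_scenario()].
#' @param bootstrap_reps number of bootstrap resamples (`>= 1`).
#' @param seed seed for the bootstrap.
#' @param conf confidence level for the bootstrap interval.
#' @return An object of class `scenario_summary`: a list with elements
#'   `label`, `n`, `replicates`, `metrics` (data frame with columns
#'   `metric`, `mean`, `median`, `p5`, `p95`), `exceedance` (list with
#'   `probability`, `ci_lower`, `ci_upper`), `truth_reference` and
#'   `analytic_expected_brier` (NA when no closed form exists).
#' @export
summarize_scenario <- function(table, bootstrap_reps = 1000L, seed = NULL,
                               conf = 0.95) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_validation("`table` must be a non-empty replicate table")
  }
  if (!is.numeric(bootstrap_reps) || bootstrap_reps < 1) {
    stop_validation("`bootstrap_reps` must be >= 1")
  }
  metric_cols <- intersect(
    c("brier", "brier_perfect", "cil", "prevalence_reference", "gap"),
    names(table))
  qs <- function(v) stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE,
                                    type = 7)
  metrics <- do.call(rbind, lapply(metric_cols, function(cn) {
    v <- table[[cn]]
    z <- qs(v)
    data.frame(metric = cn, mean = mean(v), median = z[2L],
               p5 = z[1L], p95 = z[3L])
  }))
  ex <- table$exceed
  prob <- mean(ex)
  alpha <- (1 - conf) / 2
  boot <- with_seed(seed, {
    R <- length(ex)
    vapply(seq_len(as.integer(bootstrap_reps)),
           function(i) mean(ex[sample.int(R, R, replace = TRUE)]),
           numeric(1))
  })
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  spec <- attr(table, "scenario")
  tref <- NA_real_
  aeb <- NA_real_
  if (!is.null(spec)) {
    mu <- truth_mean(spec$truth)
    tref <- mu - mu^2
    aeb <- analytic_expected_brier(spec$truth, spec$perturbation)
  }
  structure(list(label = if (is.null(spec)) NA_character_ else spec$label,
                 n = if (is.null(spec)) NA_integer_ else spec$n,
                 replicates = nrow(table),
                 metrics = metrics,
                 exceedance = list(probability = prob,
                                   ci_lower = ci[1L], ci_upper = ci[2L]),
                 truth_reference = tref,
                 analytic_expected_brier = aeb),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("<scenario_summary> %s (n = %s, %d replicates)\n",
              x$label, x$n, x$replicates))
  print(x$metrics, row.names = FALSE)
  cat(sprintf("exceedance P(ybar - ybar^2 > BS) = %.4g [%.4g, %.4g]\n",
              x$exceedance$probability, x$exceedance$ci_lower,
              x$exceedance$ci_upper))
  if (!is.na(x$truth_reference)) {
    cat(sprintf("truth reference qbar - qbar^2 = %.4g; analytic E[BS] = %.4g\n",
                x$truth_reference, x$analytic_expected_brier))
  }
  invisible(x)
}

#' Analytic expected Brier score of a scenario
#'
#' The expectation of the observed Brier score over both the truth draw and
#' the outcomes: `E[q(1-q)]` under the truth family plus the expected
#' squared perturbation — `0` for identity, `magnitude^2` for additive
#' bias, `magnitude^2 / 3` for uniform noise (second moment of
#' `Unif(-m, m)`). The additive terms assume perturbed values stay inside
#' \[0, 1\]; clamping shifts the truth-plus-noise expectation by well under
#' 0.002 at the default magnitudes. No closed form exists for logit-scale
#' noise (`NA` returned).
#'
#' @param truth a [truth_spec()].
#' @param perturbation a [perturbation_spec()]; default identity.
#' @return Numeric scalar (or `NA` for logit noise).
#' @examples
#' analytic_expected_brier(truth_spec("uniform", n = 1),
#'                         perturbation_spec("uniform_noise", 0.1))  # 1/6 + 0.01/3
#' @export
analytic_expected_brier <- function(truth,
                                    perturbation = perturbation_spec("identity")) {
  if (!inherits(truth, "truth_spec")) stop_validation("`truth` must be a truth_spec")
  if (!inherits(perturbation, "perturbation_spec")) {
    stop_validation("`perturbation` must be a perturbation_spec")
  }
  base <- truth_mean(truth) - truth_second_moment(truth)
  extra <- switch(perturbation$kind,
                  identity = 0,
                  additive_bias = perturbation$magnitude^2,
                  uniform_noise = perturbation$magnitude^2 / 3,
                  logit_noise = NA_real_)
  base + extra
}

#' Theoretical truth reference of a scenario
#'
#' `qbar - qbar^2` evaluated at the truth family's mean risk: the upper
#' limit of the expected Brier score of perfect predictions under that
#' truth distribution.
#'
#' @param truth a [truth_spec()].
#' @return Numeric scalar.
#' @export
analytic_truth_reference <- function(truth) {
  if (!inherits(truth, "truth_spec")) stop_validation("`truth` must be a truth_spec")
  mu <- truth_mean(truth)
  mu - mu^2
}

#' Expected Brier increase under symmetric perturbation
#'
#' For an interior truth vector `q` and a perturbation of every prediction
#' by `epsilon` (with signs given by `signs`), the excess of the expected
#' Brier score over the perfect expectation is exactly `epsilon^2`,
#' regardless of the sign pattern. Values pushed outside \[0, 1\] raise a
#' validation error — the sweep never clips silently.
#'
#' @param q a [truth_model()] or numeric probability vector.
#' @param epsilons numeric vector of non-negative perturbation sizes.
#' @param signs `"positive"`, `"negative"`, `"alternating"`, or a numeric
#'   vector of +1/-1 of the same length as `q`.
#' @return A data frame with columns `epsilon` and `expected_increase`.
#' @examples
#' epsilon_sweep(rep(0.5, 4), c(0, 0.1, 0.2))
#' @export
epsilon_sweep <- function(q, epsilons, signs = "positive") {
  q <- as_truth(q)
  if (!is.numeric(epsilons) || anyNA(epsilons) || any(epsilons < 0)) {
    stop_validation("`epsilons` must be non-negative numbers")
  }
  s <- if (is.character(signs)) {
    switch(match.arg(signs, c("positive", "negative", "alternating")),
           positive = rep(1, q$n),
           negative = rep(-1, q$n),
           alternating = rep_len(c(1, -1), q$n))
  } else {
    if (length(signs) != q$n || !all(signs %in% c(-1, 1))) {
      stop_validation("numeric `signs` must be +1/-1 of the same length as q")
    }
    as.numeric(signs)
  }
  base <- perfect_expected_brier(q)$value
  inc <- vapply(epsilons, function(eps) {
    p <- q$q + s * eps
    if (any(p < 0 | p > 1)) {
      stop_validation(sprintf(
        "epsilon = %g pushes predictions outside [0, 1]; no silent clipping in the sweep",
        eps))
    }
    expected_brier(p, q)$value - base
  }, numeric(1))
  data.frame(epsilon = as.numeric(epsilons), expected_increase = inc)
}

#' Compare two models' replicate tables
#'
#' Pairs two replicate tables from scenarios sharing the truth
#' specification and sample size, and reports how often each model attains
#' the lower (better) observed Brier score — quantifying how often the
#' worse model wins by chance.
#'
#' @param table_a,table_b `replicate_table`s of equal replicate count.
#' @return An object of class `model_comparison`: a list with win
#'   fractions, tie fraction, and the mean and median paired difference
#'   `brier_a - brier_b`.
#' @export
compare_models <- function(table_a, table_b) {
  if (!is.data.frame(table_a) || !is.data.frame(table_b)) {
    stop_validation("both inputs must be replicate tables")
  }
  if (nrow(table_a) != nrow(table_b)) {
    stop_validation("replicate counts differ; tables are not comparable")
  }
  sa <- attr(table_a, "scenario"); sb <- attr(table_b, "scenario")
  if (!is.null(sa) && !is.null(sb)) {
    if (sa$n != sb$n || !identical(sa$truth[c("family", "params")],
                                   sb$truth[c("family", "params")])) {
      stop_validation("scenarios must share the truth specification and n")
    }
  }
  d <- table_a$brier - table_b$brier
  structure(list(replicates = length(d),
                 win_a = mean(d < 0), win_b = mean(d > 0),
                 ties = mean(d == 0),
                 mean_difference = mean(d),
                 median_difference = stats::median(d)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model_comparison> %d paired replicates\n  model A wins: %.3f  model B wins: %.3f  ties: %.3f\n  mean diff (A - B): %.5g\n",
    x$replicates, x$win_a, x$win_b, x$ties, x$mean_difference))
  invisible(x)
}
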