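#' Suite run configuration
#'
#' Bundles a list of [scenario_spec()]s with bootstrap settings. Scenario
#' labels must be unique since they name the output files.
#'
#' @param scenarios list of [scenario_spec()] objects.
#' @param bootstrap_reps bootstrap resamples used when summarising.
#' @param master_seed global seed; also seeds the per-scenario bootstrap.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenarios, bootstrap_reps = 1000L, master_seed = 1L) {
  if (!is.list(scenarios) ||
      !all(vapply(scenarios, inherits, logical(1), "scenario_spec"))) {
    stop_validation("`scenarios` must be a list of scenario_spec objects")
  }
  labels <- vapply(scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_validation(sprintf("scenario labels must be unique (duplicated: %s)",
                            paste(unique(labels[duplicated(labels)]),
                                  collapse = ", ")))
  }
  structure(list(scenarios = scenarios,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d scenario(s), bootstrap_reps = %d, master_seed = %d\n",
              length(x$scenarios), x$bootstrap_reps, x$master_seed))
  for (s in x$scenarios) print(s)
  invisible(x)
}

scenario_to_list <- function(spec) {
  list(label = spec$label, n = spec$n, replicates = spec$replicates,
       master_seed = spec$master_seed, redraw_q = spec$redraw_q,
       truth = c(list(family = spec$truth$family), spec$truth$params),
       perturbation = list(kind = spec$perturbation$kind,
                           magnitude = spec$perturbation$magnitude,
                           clip_policy = spec$perturbation$clip_policy))
}

scenario_from_list <- function(x, default_seed = 1L) {
  tr <- x$truth
  if (is.null(tr$family)) stop_input("scenario entry is missing truth$family")
  targs <- tr[setdiff(names(tr), "family")]
  # yaml/json round-trips may hand back length-1 lists; flatten scalars
  targs <- lapply(targs, function(v) if (is.list(v)) unlist(v) else v)
  truth <- do.call(truth_spec,
                   c(list(family = tr$family, n = x$n %||% 300L), targs))
  pt <- x$perturbation %||% list(kind = "identity")
  pert <- perturbation_spec(kind = pt$kind %||% "identity",
                            magnitude = pt$magnitude %||% 0,
                            clip_policy = pt$clip_policy %||% "clip_to_unit")
  scenario_spec(truth = truth, perturbation = pert,
                n = x$n %||% 300L,
                replicates = x$replicates %||% 5000L,
                master_seed = x$master_seed %||% default_seed,
                label = x$label %||% "scenario",
                redraw_q = x$redraw_q %||% TRUE)
}

#' Read a suite configuration from YAML or JSON
#'
#' The file holds `bootstrap_reps`, `master_seed` and a `scenarios` list
#' whose entries mirror [scenario_spec()] fields (`label`, `n`,
#' `replicates`, `master_seed`, `redraw_q`, a `truth` block with `family`
#' plus family parameters, and a `perturbation` block with `kind`,
#' `magnitude`, `clip_policy`). Scenarios missing a `master_seed` get
#' deterministic seeds derived from the global one.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @seealso [write_run_config()], [default_suite_config()]
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  master_seed <- as.integer(raw$master_seed %||% 1L)
  scen_raw <- raw$scenarios %||% list()
  scenarios <- lapply(seq_along(scen_raw), function(i) {
    scenario_from_list(scen_raw[[i]], default_seed = master_seed + i)
  })
  run_config(scenarios,
             bootstrap_reps = raw$bootstrap_reps %||% 1000L,
             master_seed = master_seed)
}

#' Write a suite configuration to YAML or JSON
#'
#' @param config a [run_config()].
#' @param path output path; format chosen from the extension.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) stop_validation("`config` must be a run_config")
  x <- list(master_seed = config$master_seed,
            bootstrap_reps = config$bootstrap_reps,
            scenarios = lapply(config$scenarios, scenario_to_list))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Default misconception-suite configuration
#'
#' The shipped scenario grid covers every truth family and perturbation the
#' misconception demonstrations use: uniform, beta, two-point, constant and
#' emulated logistic-model truths, with perfect predictions, additive bias,
#' uniform noise and logit-scale noise, at sample sizes 300 and 1000 with
#' 5000 replicates (200 under `smoke`, intended for quick runs).
#'
#' @param master_seed global seed for the suite.
#' @param smoke if TRUE, scale every scenario down to 200 replicates.
#' @return A [run_config()].
#' @export
default_suite_config <- function(master_seed = 1L, smoke = FALSE) {
  reps <- if (isTRUE(smoke)) 200L else 5000L
  nh <- nhanes_like_spec(0.2, k = 3L, beta = rep(0.5, 3), n = 1000L,
                         seed = master_seed)
  mk <- function(i, label, truth, pert, n, redraw_q = TRUE) {
    scenario_spec(truth = truth, perturbation = pert, n = n,
                  replicates = reps, master_seed = master_seed + i,
                  label = label, redraw_q = redraw_q)
  }
  unif <- function(n) truth_spec("uniform", n = n)
  beta13 <- function(n) truth_spec("beta", n = n, shape1 = 1, shape2 = 3)
  ident <- perturbation_spec("identity")
  noise01 <- perturbation_spec("uniform_noise", 0.1)
  scenarios <- list(
    mk(1L, "misconception1_uniform_perfect_n1000", unif(1000), ident, 1000L),
    mk(2L, "misconception1_uniform_noise_n1000", unif(1000), noise01, 1000L),
    mk(3L, "misconception1_nhanes_perfect_n1000", nh, ident, 1000L,
       redraw_q = FALSE),
    mk(4L, "misconception2_beta_noise_n1000", beta13(1000), noise01, 1000L),
    mk(5L, "misconception2_two_point_perfect_n300",
       truth_spec("two_point", n = 300), ident, 300L),
    mk(6L, "misconception3_bias_n300", unif(300),
       perturbation_spec("additive_bias", 0.1), 300L),
    mk(7L, "misconception3_logit_noise_n300", unif(300),
       perturbation_spec("logit_noise", 0.5), 300L),
    mk(8L, "misconception4_constant_half_n300",
       truth_spec("constant", n = 300, value = 0.5), ident, 300L),
    mk(9L, "misconception5_uniform_perfect_n300", unif(300), ident, 300L),
    mk(10L, "misconception5_beta_perfect_n300", beta13(300), ident, 300L)
  )
  run_config(scenarios, bootstrap_reps = 1000L, master_seed = master_seed)
}

#' Analytic worked examples
#'
#' The closed-form quantities behind the misconception demonstrations,
#' computed from the metrics module: the one-observation model comparison
#' (expected scores 0.1 vs 0.1125 at true risk 0.1), the cross-dataset
#' perfect expectations (0.25 for constant one-half truth, 1/6 for uniform,
#' 0 for the two-point 0/1 truth), the uniform-noise scenario expectation
#' 1/6 + 0.01/3, the two-setting calibration example (both settings have
#' expected Brier 0.21 by the decomposition, while expected CIL is 0 vs
#' 0.2224745), the prevalence references at incidence 0.5 and 0.1, and the
#' epsilon-squared perturbation increase.
#'
#' Note on the calibration example: the biased setting's expected Brier
#' score is often quoted as 0.2, but the exact decomposition
#' `(1/n) sum (p_i - q_i)^2 + q_i(1 - q_i)` for `p = (0.444949, 1)`,
#' `q = (0.2, 0.8)` gives `(0.06 + 0.16 + 0.04 + 0.16)/2 = 0.21`; this
#' function reports the computed value.
#'
#' @return A data frame with columns `group`, `name`, `value`.
#' @export
analytic_examples <- function() {
  ex <- list(
    list("worked_example_m2", "model1_expected_brier",
         expected_brier(0, 0.1)$value),
    list("worked_example_m2", "model2_expected_brier",
         expected_brier(0.25, 0.1)$value),
    list("misconception2", "perfect_constant_half_expected_brier",
         perfect_expected_brier(0.5)$value),
    list("misconception2", "perfect_uniform_expected_brier",
         analytic_expected_brier(truth_spec("uniform", n = 1))),
    list("misconception2", "perfect_two_point_expected_brier",
         analytic_expected_brier(truth_spec("two_point", n = 1))),
    list("misconception2", "uniform_noise_expected_brier",
         analytic_expected_brier(truth_spec("uniform", n = 1),
                                 perturbation_spec("uniform_noise", 0.1))),
    list("example1", "setting_a_expected_brier",
         expected_brier(c(0.3, 0.7), c(0.3, 0.7))$value),
    list("example1", "setting_a_expected_cil",
         expected_cil(c(0.3, 0.7), c(0.3, 0.7))$value),
    list("example1", "setting_b_expected_brier",
         expected_brier(c(0.444949, 1), c(0.2, 0.8))$value),
    list("example1", "setting_b_expected_cil",
         expected_cil(c(0.444949, 1), c(0.2, 0.8))$value),
    list("misconception4", "prevalence_reference_incidence_0.5",
         prevalence_reference(rep(c(0, 1), 5))$value),
    list("misconception4", "prevalence_reference_incidence_0.1",
         prevalence_reference(c(1, rep(0, 9)))$value),
    list("main_properties", "epsilon_0.1_expected_increase",
         epsilon_sweep(rep(0.5, 10), 0.1)$expected_increase)
  )
  data.frame(group = vapply(ex, `[[`, character(1), 1L),
             name = vapply(ex, `[[`, character(1), 2L),
             value = vapply(ex, `[[`, numeric(1), 3L))
}

#' Run the full simulation suite
#'
#' Executes every scenario in the configuration, writes per-scenario
#' replicate and summary CSVs plus one structured JSON report, and returns
#' the report. The report pairs each scenario's empirical summary with its
#' analytic expectation so the Monte-Carlo consistency gap is auditable,
#' and always includes the analytic worked examples. Failures of individual
#' scenarios are caught, logged and collected; callers (e.g. the CLI) can
#' turn a non-empty `failures` element into a nonzero exit status.
#'
#' Output files per scenario `label`: `label_replicates.csv` and
#' `label_summary.csv`; suite-wide: `suite_report.json` and
#' `analytic_examples.csv`. Reruns with the same configuration produce
#' byte-identical CSVs.
#'
#' @param config a [run_config()], or a path to a YAML/JSON configuration.
#' @param out_dir output directory (created if missing); NULL disables file
#'   output.
#' @param smoke if TRUE, scale every scenario to at most 200 replicates.
#' @param verbose print per-scenario progress with seeds echoed.
#' @return An object of class `suite_report` (invisibly): list with
#'   `scenarios` (per-label summaries), `analytic_examples`, `failures`.
#' @export
run_suite <- function(config, out_dir = NULL, smoke = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    stop_validation("`config` must be a run_config or a path to one")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  summaries <- list()
  failures <- list()
  for (spec in config$scenarios) {
    if (isTRUE(smoke) && spec$replicates > 200L) spec$replicates <- 200L
    if (verbose) {
      message(sprintf("scenario %s: n = %d, %d replicates, master_seed = %d",
                      spec$label, spec$n, spec$replicates, spec$master_seed))
    }
    res <- tryCatch({
      tab <- run_scenario(spec)
      summ <- summarize_scenario(tab, bootstrap_reps = config$bootstrap_reps,
                                 seed = spec$master_seed + 104729L)
      if (!is.null(out_dir)) {
        utils::write.csv(as.data.frame(tab),
                         file.path(out_dir, paste0(spec$label, "_replicates.csv")),
                         row.names = FALSE)
        utils::write.csv(cbind(label = spec$label, summ$metrics),
                         file.path(out_dir, paste0(spec$label, "_summary.csv")),
                         row.names = FALSE)
      }
      summ
    }, briersim_error = function(e) e)
    if (inherits(res, "error")) {
      failures[[spec$label]] <- conditionMessage(res)
      if (verbose) message(sprintf("scenario %s FAILED: %s", spec$label,
                                   conditionMessage(res)))
    } else {
      summaries[[spec$label]] <- res
    }
  }
  analytic <- analytic_examples()
  report <- structure(
    list(scenarios = lapply(summaries, function(s) {
      list(label = s$label, n = s$n, replicates = s$replicates,
           metrics = s$metrics,
           exceedance = s$exceedance,
           truth_reference = s$truth_reference,
           analytic_expected_brier = s$analytic_expected_brier)
    }),
    analytic_examples = analytic,
    failures = failures),
    class = "suite_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "suite_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    utils::write.csv(analytic, file.path(out_dir, "analytic_examples.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}

#' @export
print.suite_report <- function(x, ...) {
  cat(sprintf("<suite_report> %d scenario(s), %d failure(s)\n",
              length(x$scenarios), length(x$failures)))
  for (s in x$scenarios) {
    b <- s$metrics[s$metrics$metric == "brier", ]
    cat(sprintf("  %s: median BS %.4g [%.4g, %.4g], analytic E[BS] %.4g\n",
                s$label, b$median, b$p5, b$p95, s$analytic_expected_brier))
  }
  if (length(x$failures)) {
    cat("failures:\n")
    for (nm in names(x$failures)) cat(sprintf("  %s: %s\n", nm, x$failures[[nm]]))
  }
  invisible(x)
}

#' Evaluate a file or table of predictions
#'
#' Reports, for paired predictions and outcomes, the observed Brier score
#' with a percentile-bootstrap 95% confidence interval (resampling
#' `(p_i, y_i)` pairs), the scaled Brier score against the prevalence
#' baseline, calibration-in-the-large, and the prevalence reference
#' `ybar - ybar^2`. When all outcomes are identical the scaled Brier score
#' is reported as `NA` with a note, since its prevalence baseline is zero.
#'
#' @param input a CSV path (header `p,y`), data frame with columns `p` and
#'   `y`, or a [prediction_set()].
#' @param bootstrap_reps bootstrap resamples for the Brier CI.
#' @param seed seed for the bootstrap.
#' @param conf confidence level.
#' @return An object of class `prediction_report`: list with `metrics` (a
#'   [metric_table()] data frame), `brier_ci` (length-2 vector), `notes`.
#' @examples
#' df <- data.frame(p = c(0.2, 0.8, 0.5, 0.5), y = c(0, 1, 1, 0))
#' evaluate_predictions(df, bootstrap_reps = 200, seed = 1)
#' @export
evaluate_predictions <- function(input, bootstrap_reps = 1000L, seed = NULL,
                                 conf = 0.95) {
  ps <- if (inherits(input, "prediction_set")) {
    input
  } else if (is.data.frame(input)) {
    if (!all(c("p", "y") %in% names(input))) {
      stop_input("data frame must have columns `p` and `y`")
    }
    prediction_set(input$p, input$y)
  } else if (is.character(input)) {
    read_predictions(input)
  } else {
    stop_input("`input` must be a path, data frame or prediction_set")
  }
  if (!is.numeric(bootstrap_reps) || bootstrap_reps < 1) {
    stop_validation("`bootstrap_reps` must be >= 1")
  }
  notes <- character(0)
  bs <- brier_score(ps)
  sb <- tryCatch(scaled_brier(ps), briersim_undefined_reference = function(e) {
    notes <<- c(notes, paste("scaled Brier score unavailable:",
                             conditionMessage(e)))
    metric_value("scaled_brier", NA_real_, ps$n)
  })
  metrics <- metric_table(bs, sb, calibration_in_the_large(ps),
                          prevalence_reference(ps$y))
  alpha <- (1 - conf) / 2
  boot <- with_seed(seed, {
    vapply(seq_len(as.integer(bootstrap_reps)), function(i) {
      idx <- sample.int(ps$n, ps$n, replace = TRUE)
      mean((ps$p[idx] - ps$y[idx])^2)
    }, numeric(1))
  })
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(metrics = metrics, brier_ci = ci, conf = conf,
                 bootstrap_reps = as.integer(bootstrap_reps), notes = notes),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  print(x$metrics, row.names = FALSE)
  cat(sprintf("Brier score %g%% bootstrap CI: [%.5g, %.5g] (%d resamples)\n",
              100 * x$conf, x$brier_ci[1L], x$brier_ci[2L], x$bootstrap_reps))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
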