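#' Paired predictions and binary outcomes
#'
#' Container for a set of probabilistic predictions `p` and the observed
#' binary outcomes `y` they are scored against. Both vectors must have the
#' same length `n >= 1`, every `p[i]` must lie in \[0, 1\] and every `y[i]`
#' must be 0 or 1.
#'
#' @param p numeric vector of predicted event probabilities.
#' @param y numeric vector of observed outcomes, coded 0/1.
#' @return An object of class `prediction_set`: a list with elements `p`,
#'   `y` and `n`.
#' @seealso [brier_score()], [calibration_in_the_large()], [scaled_brier()],
#'   [read_predictions()]
#' @examples
#' ps <- prediction_set(p = c(0.2, 0.8, 0.5, 0.5), y = c(0, 1, 1, 0))
#' brier_score(ps)
#' @export
prediction_set <- function(p, y) {
  p <- check_probability(p, "p")
  y <- check_binary(y, "y")
  check_same_length(p, y, "`p` and `y`")
  structure(list(p = p, y = y, n = length(p)), class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> n = %d, mean(p) = %.4g, mean(y) = %.4g\n",
              x$n, mean(x$p), mean(x$y)))
  invisible(x)
}

#' Vector of true event probabilities
#'
#' Holds the (in practice unobservable) individual risks `q` under which
#' outcomes arise as independent Bernoulli draws `Y_i ~ Bern(q_i)`, together
#' with a free-text descriptor of the generating distribution.
#'
#' @param q numeric vector of true probabilities, each in \[0, 1\].
#' @param source character descriptor of how `q` was generated.
#' @return An object of class `truth_model`: a list with elements `q`,
#'   `source` and `n`.
#' @seealso [sample_true_probabilities()], [expected_brier()],
#'   [perfect_expected_brier()]
#' @examples
#' tm <- truth_model(c(0.3, 0.7))
#' perfect_expected_brier(tm)
#' @export
truth_model <- function(q, source = "unspecified") {
  q <- check_probability(q, "q")
  structure(list(q = q, source = as.character(source)[1L], n = length(q)),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf("<truth_model> n = %d, source = %s, mean(q) = %.4g\n",
              x$n, x$source, mean(x$q)))
  invisible(x)
}

# Accept either a truth_model or a bare probability vector.
as_truth <- function(q) {
  if (inherits(q, "truth_model")) return(q)
  truth_model(q)
}

#' A named metric value
#'
#' Lightweight record returned by all metric functions: the metric
#' identifier, its numeric value, and the sample size it was computed on.
#'
#' @param name metric identifier.
#' @param value numeric scalar.
#' @param n sample size used.
#' @return An object of class `metric_value`.
#' @export
metric_value <- function(name, value, n) {
  structure(list(name = as.character(name)[1L],
                 value = as.numeric(value)[1L],
                 n = as.integer(n)[1L]),
            class = "metric_value")
}

#' @export
print.metric_value <- function(x, ...) {
  cat(sprintf("%s = %.7g (n = %d)\n", x$name, x$value, x$n))
  invisible(x)
}

#' @export
as.numeric.metric_value <- function(x, ...) x$value

#' Collect metric values into a data frame
#'
#' @param ... `metric_value` objects (or a single list of them).
#' @return A data frame with columns `metric`, `value`, `n`.
#' @examples
#' ps <- prediction_set(c(0.2, 0.8), c(0, 1))
#' metric_table(brier_score(ps), calibration_in_the_large(ps))
#' @export
metric_table <- function(...) {
  mv <- list(...)
  if (length(mv) == 1L && !inherits(mv[[1L]], "metric_value")) mv <- mv[[1L]]
  stopifnot(all(vapply(mv, inherits, logical(1), "metric_value")))
  data.frame(metric = vapply(mv, `[[`, character(1), "name"),
             value = vapply(mv, `[[`, numeric(1), "value"),
             n = vapply(mv, `[[`, integer(1), "n"))
}

#' Read predictions and outcomes from a CSV file
#'
#' Expects a header with columns `p` (predicted probability) and `y`
#' (binary outcome). Malformed rows are reported with their file line
#' numbers (header is line 1).
#'
#' @param path path to a CSV file.
#' @return A [prediction_set()].
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("p", "y") %in% names(df))) {
    stop_input(sprintf("%s must have header columns `p` and `y`", path))
  }
  p <- suppressWarnings(as.numeric(df$p))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(p) | is.na(y) | p < 0 | p > 1 | !(y %in% c(0, 1)))
  if (length(bad) > 0L) {
    stop_validation(sprintf(
      "invalid rows in %s at line(s) %s: p must be in [0,1], y in {0,1}",
      path, paste(bad + 1L, collapse = ", ")))
  }
  prediction_set(p, y)
}

#' Write metric values to CSV
#'
#' @param metrics a data frame from [metric_table()] or a list of
#'   `metric_value` objects.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (!is.data.frame(metrics)) metrics <- metric_table(metrics)
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
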