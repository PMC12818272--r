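# Internal helpers: condition constructors, seeded evaluation, numeric checks.

stop_briersim <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "briersim_error", "error")))
}

stop_validation <- function(msg) stop_briersim(msg, "briersim_validation_error")
stop_input <- function(msg) stop_briersim(msg, "briersim_input_error")

#' @noRd
check_probability <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 1L) stop_input(sprintf("`%s` must be non-empty", name))
  if (!is.numeric(x) || anyNA(x)) {
    stop_validation(sprintf("`%s` must be numeric without missing values", name))
  }
  if (any(x < 0 | x > 1)) {
    stop_validation(sprintf("`%s` must lie in [0, 1]", name))
  }
  as.numeric(x)
}

#' @noRd
check_binary <- function(y, name = "y") {
  if (length(y) < 1L) stop_input(sprintf("`%s` must be non-empty", name))
  if (!is.numeric(y) || anyNA(y) || !all(y %in% c(0, 1))) {
    stop_validation(sprintf("`%s` must contain only 0 and 1", name))
  }
  as.numeric(y)
}

#' @noRd
check_same_length <- function(a, b, what = "vectors") {
  if (length(a) != length(b)) {
    stop_validation(sprintf("%s must have equal length (%d vs %d)",
                            what, length(a), length(b)))
  }
  invisible(TRUE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  A NULL seed uses (and advances) the
# current stream, so callers can either pass explicit seeds or manage one
# stream themselves.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_validation("`seed` must be a single integer or NULL")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-replicate child seeds: one master seed spawns an
# order-independent vector of substream seeds, so replicates can run in any
# order and still match a sequential run.
child_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Log-odds and inverse log-odds
#'
#' Thin wrappers around [stats::qlogis()] and [stats::plogis()] used for the
#' symmetric logit-scale perturbation. `expit(logit(0)) == 0` and
#' `expit(logit(1)) == 1`, so degenerate probabilities are fixed points.
#'
#' @param p probability in \[0, 1\].
#' @param x real number (log-odds).
#' @return `logit()` returns log-odds (`-Inf`/`Inf` at the boundary);
#'   `expit()` returns a probability.
#' @examples
#' expit(logit(0.3))
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
expit <- function(x) stats::plogis(x)
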