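test_that("observed Brier score matches hand-computed values and validates input", {
  expect_equal(brier_score(prediction_set(c(1, 0), c(1, 0)))$value, 0)
  expect_equal(brier_score(prediction_set(0.5, 1))$value, 0.25)
  # (0.04 + 0.04 + 0.25 + 0.25) / 4
  ps <- prediction_set(c(0.2, 0.8, 0.5, 0.5), c(0, 1, 1, 0))
  expect_equal(brier_score(ps)$value, 0.145)
  expect_equal(brier_score(ps)$n, 4L)

  expect_error(prediction_set(numeric(0), numeric(0)),
               class = "briersim_input_error")
  expect_error(prediction_set(c(0.5, 1.2), c(0, 1)),
               class = "briersim_validation_error")
  expect_error(prediction_set(c(0.5, 0.5), c(0, 2)),
               class = "briersim_validation_error")
  expect_error(prediction_set(c(0.5, 0.5), 1),
               class = "briersim_validation_error")
})

test_that("expected Brier score reproduces the one-observation model comparison", {
  expect_equal(expected_brier(0, 0.1)$value, 0.1)
  expect_equal(expected_brier(0.25, 0.1)$value, 0.1125)
  expect_equal(expected_brier(c(0.3, 0.7), c(0.3, 0.7))$value, 0.21)
  expect_error(expected_brier(c(0.1, 0.2), 0.5),
               class = "briersim_validation_error")
})

test_that("perfect-prediction expectation covers the three cross-dataset cases", {
  expect_equal(perfect_expected_brier(rep(0.5, 7))$value, 0.25)
  expect_equal(perfect_expected_brier(c(0, 1, 1, 0, 1))$value, 0)
  expect_equal(perfect_expected_brier(c(0.2, 0.8))$value, 0.16)
  q <- c(0.1, 0.35, 0.9)
  expect_equal(perfect_expected_brier(q)$value, expected_brier(q, q)$value)
})

test_that("prevalence and truth references follow ybar - ybar^2 and qbar - qbar^2", {
  expect_equal(prevalence_reference(rep(c(0, 1), 8))$value, 0.25)
  expect_equal(prevalence_reference(c(1, rep(0, 9)))$value, 0.090)
  expect_equal(prevalence_reference(rep(0, 5))$value, 0)

  expect_equal(truth_reference(rep(0.5, 3))$value, 0.25)
  expect_equal(truth_reference(c(0.2, 0.8))$value, 0.25)
  expect_equal(truth_reference(c(0, 1))$value, 0.25)
  # strictly above the perfect expectation when q is non-constant
  expect_gt(truth_reference(c(0.2, 0.8))$value,
            perfect_expected_brier(c(0.2, 0.8))$value)
})

test_that("calibration-in-the-large and its expectation reproduce the two-setting example", {
  y <- c(0, 1, 1, 0)
  expect_equal(calibration_in_the_large(prediction_set(y, y))$value, 0)
  expect_equal(expected_cil(c(0.3, 0.7), c(0.3, 0.7))$value, 0)
  expect_equal(expected_cil(c(0.444949, 1), c(0.2, 0.8))$value, 0.2224745)
  q <- c(0.2, 0.4, 0.6)
  expect_equal(expected_cil(q + 0.05, q)$value, 0.05)
})

test_that("scaled Brier score rescales against the prevalence baseline", {
  y <- c(0, 1, 1, 0)
  expect_equal(scaled_brier(prediction_set(y, y))$value, 1)
  # constant prediction at the incidence scores exactly 0
  expect_equal(scaled_brier(prediction_set(rep(0.5, 4), y))$value, 0)
  expect_equal(scaled_brier(prediction_set(c(0.2, 0.8, 0.5, 0.5), y))$value,
               1 - 0.145 / 0.25)
  expect_error(scaled_brier(prediction_set(c(0.2, 0.3), c(0, 0))),
               class = "briersim_undefined_reference")
})

test_that("l2 distance is the rooted Euclidean distance", {
  expect_equal(l2_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(l2_distance(c(0, 0), c(1, 1)), sqrt(2))
  expect_equal(l2_distance(0.25, 0.1), 0.15)
  expect_error(l2_distance(c(0.1, 0.2), 0.3),
               class = "briersim_validation_error")
})

test_that("decomposition identity: E[BS] = perfect term + l2^2 / n", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    p <- random_probability_vector(n)
    q <- random_probability_vector(n)
    expect_equal(expected_brier(p, q)$value,
                 perfect_expected_brier(q)$value + l2_distance(p, q)^2 / n,
                 tolerance = 1e-12)
  }
})

test_that("expected Brier ordering matches the l2 ordering on random triples", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    p <- random_probability_vector(n)
    p2 <- random_probability_vector(n)
    q <- random_probability_vector(n)
    expect_identical(l2_distance(p, q) < l2_distance(p2, q),
                     expected_brier(p, q)$value < expected_brier(p2, q)$value)
  }
})

test_that("epsilon perturbation raises the expectation by exactly epsilon^2", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:10, 1)
    q <- runif(n, 0.25, 0.75)
    eps <- runif(1, 0, 0.2)
    s <- sample(c(-1, 1), n, replace = TRUE)
    expect_equal(
      expected_brier(q + s * eps, q)$value - perfect_expected_brier(q)$value,
      eps^2, tolerance = 1e-12)
  }
})

test_that("Jensen bound: perfect expectation <= qbar - qbar^2, equal iff q constant", {
  set.seed(3)
  for (i in 1:50) {
    q <- random_probability_vector(sample(2:30, 1))
    expect_lte(perfect_expected_brier(q)$value, truth_reference(q)$value)
    if (stats::var(q) > 1e-12) {
      expect_lt(perfect_expected_brier(q)$value, truth_reference(q)$value)
    }
  }
  q <- rep(0.37, 12)
  expect_equal(perfect_expected_brier(q)$value, truth_reference(q)$value)
})

test_that("Monte-Carlo mean of observed scores matches the exact expectation", {
  set.seed(99)
  q <- runif(100)
  p <- pmin(pmax(q + runif(100, -0.1, 0.1), 0), 1)
  mc <- mc_expected_brier(p, q, replicates = 5000, seed = 123)
  expect_lt(abs(mc$mean - expected_brier(p, q)$value), 4 * mc$se)
})

test_that("metric tables round-trip to CSV", {
  ps <- prediction_set(c(0.2, 0.8), c(0, 1))
  tab <- metric_table(brier_score(ps), calibration_in_the_large(ps))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(tab, path)
  back <- read.csv(path)
  expect_equal(back$metric, c("brier_score", "cil"))
  expect_equal(back$value, tab$value)
})
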