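Package: briersim
Title: Brier Score Properties and Monte Carlo Evaluation for Binary Risk
    Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating probabilistic predictions of binary
    outcomes with the Brier score and its companion quantities. Provides
    exact expectation formulas for the Brier score under Bernoulli
    outcomes (including the perfect-prediction expectation, the
    prevalence reference, calibration-in-the-large and the scaled Brier
    score), deterministic and stochastic perturbation models mapping true
    risks to predictions, synthetic truth-distribution generators
    (constant, uniform, beta, two-point and an emulated
    logistic-regression model), a seeded Monte Carlo simulation engine
    with percentile summaries and bootstrap uncertainty, and a
    configuration-driven pipeline that reproduces classical
    demonstrations of how realised Brier scores can mislead.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
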