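# briersim

Tools for evaluating probabilistic predictions of binary clinical outcomes
with the Brier score — and for understanding what an observed score does
and does not mean.

The Brier score of predictions `p` against outcomes `y` is

    BS(p, y) = (1/n) * sum_i (p_i - y_i)^2.

When outcomes arise as independent Bernoulli draws `Y_i ~ Bern(q_i)` from
true risks `q`, its expectation decomposes exactly as

    E[BS] = (1/n) * sum_i [ (p_i - q_i)^2 + q_i (1 - q_i) ],

squared distance from the truth plus irreducible outcome variance. This has
consequences practitioners routinely trip over: a perfect model
(`p = q`) does not score zero; scores are not comparable across populations
with different risk distributions; a low score is not evidence of
calibration; a score near the prevalence baseline `ybar - ybar^2` does not
prove the model useless; and the score can exceed that baseline by chance.
`briersim` implements the exact expectation formulas, the companion metrics
(calibration-in-the-large, scaled Brier score, prevalence and truth
references), perturbation models mapping true risks to predictions,
synthetic truth-distribution generators, and a seeded Monte-Carlo engine
that reproduces each of these demonstrations from scratch.

Intended users: biostatisticians and epidemiologists validating risk
prediction models, and anyone teaching or studying proper scoring rules.

## Worked example

Score a file (or data frame) of predictions against outcomes, with a
prevalence baseline and a bootstrap confidence interval:

```r
library(briersim)
path <- system.file("extdata", "example_predictions.csv", package = "briersim")
evaluate_predictions(path, bootstrap_reps = 500, seed = 3)
#>                metric     value  n
#>           brier_score 0.1309510 40
#>          scaled_brier 0.1815561 40
#>                   cil 0.0794400 40
#>  prevalence_reference 0.1600000 40
#> Brier score 95% bootstrap CI: [0.086549, 0.17919] (500 resamples)
```

The score (0.131) beats the constant-prevalence baseline (0.160), so the
scaled Brier score is positive (0.18); the positive CIL (0.079) says the
predictions overestimate the event rate on average — information the Brier
score alone cannot provide.

Simulate a scenario: true risks uniform on (0, 1), predictions perturbed by
independent Unif(−0.1, 0.1) noise, n = 300, 1000 Monte-Carlo replicates:

```r
spec <- scenario_spec(truth_spec("uniform", n = 300),
                      perturbation_spec("uniform_noise", 0.1),
                      n = 300, replicates = 1000, master_seed = 42,
                      label = "uniform_noise_n300")
tab <- run_scenario(spec)
summarize_scenario(tab, bootstrap_reps = 1000, seed = 42)
#> <scenario_summary> uniform_noise_n300 (n = 300, 1000 replicates)
#>                metric         mean       median          p5        p95
#>                 brier 0.1695271688 1.696345e-01  0.15043912 0.18933584
#>         brier_perfect 0.1664493855 1.664070e-01  0.14828932 0.18572605
#>                   cil 0.0005510333 2.291074e-06 -0.04018079 0.03876122
#>  prevalence_reference 0.2491310000 2.496000e-01  0.24678889 0.24998889
#>                   gap 0.0826816145 8.278067e-02  0.06370374 0.10102470
#> exceedance P(ybar - ybar^2 > BS) = 1 [1, 1]
#> truth reference qbar - qbar^2 = 0.25; analytic E[BS] = 0.17
```

The replicate mean (0.1695) sits on the analytic expectation
`E[q(1-q)] + m^2/3 = 1/6 + 0.01/3 ≈ 0.17`, and even the *perfect*
predictions average 0.166 — far from zero — because the outcome variance is
irreducible. The full misconception suite (ten scenarios covering every
truth family and perturbation, with per-scenario CSVs and a JSON report)
runs via `run_suite(default_suite_config())` or the command-line wrapper:

```sh
Rscript inst/cli/briersim.R simulate --smoke --out output_dir
Rscript inst/cli/briersim.R evaluate --input predictions.csv
```

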