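---
title: "Evaluating binary risk predictions with the Brier score: models, simulation design and pitfalls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating binary risk predictions with the Brier score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(briersim)
```

## The model

A clinical prediction model assigns each subject a probability $p_i$ of a
binary event; the observed outcomes are modelled as independent Bernoulli
draws $Y_i \sim \mathrm{Bern}(q_i)$ from unobservable true risks
$q_i \in [0,1]$. The Brier score of the predictions is

$$\mathrm{BS}(p, y) = \frac{1}{n}\sum_{i=1}^n (p_i - y_i)^2,$$

a strictly proper scoring rule: its expectation over the outcomes,

$$\mathrm{E}[\mathrm{BS}] = \frac{1}{n}\sum_{i=1}^n
  \left[(p_i - q_i)^2 + q_i(1 - q_i)\right],$$

is uniquely minimised at $p = q$, where it equals the *perfect expectation*
$\frac{1}{n}\sum_i q_i(1-q_i)$. This decomposition — squared distance from
the truth plus irreducible Bernoulli variance — is the analytical core of
the package (`expected_brier()`, `perfect_expected_brier()`), and everything
else follows from it:

* Perturbing every prediction by $\varepsilon$ (either sign, per
  coordinate) raises the expectation by exactly $\varepsilon^2$
  (`epsilon_sweep()`).
* The expectation preserves the Euclidean-distance ordering of prediction
  vectors to the truth (`l2_distance()`); `l2_distance()` returns the
  *rooted* distance, and the decomposition uses its square divided by $n$ —
  the two conventions induce the same ordering.
* By Jensen's inequality the perfect expectation is bounded above by
  $\bar q - \bar q^2$ (`truth_reference()`), with equality exactly for
  constant risks; the observable counterpart $\bar y - \bar y^2$
  (`prevalence_reference()`) is the Brier score of the constant prediction
  $p_i = \bar y$ and serves as the non-informative baseline, also used by
  the scaled Brier score $1 - \mathrm{BS}/(\bar y(1-\bar y))$
  (`scaled_brier()`).
* Calibration-in-the-large is implemented in difference form,
  $\mathrm{CIL} = \overline{p} - \overline{y}$ (`calibration_in_the_large()`),
  with expectation $\overline{p} - \overline{q}$ (`expected_cil()`). The
  difference form was chosen over the logistic-intercept variant because it
  is the definition under which the two-setting worked example evaluates to
  exactly $0$ and $0.2224745$; the intercept variant is out of scope.

### A known inconsistency in the two-setting example

The classical two-setting calibration example takes
$q = p = (0.3, 0.7)$ (Setting A) versus $q' = (0.2, 0.8)$,
$p' = (0.444949, 1)$ (Setting B). Setting A has expected Brier score
$0.21$ and expected CIL $0$; Setting B has expected CIL $0.2224745$ and is
usually quoted with an expected Brier score of $0.2$. The exact
decomposition, however, gives
$\big((0.444949-0.2)^2 + 0.16 + (1-0.8)^2 + 0.16\big)/2 = 0.21$
(note $0.444949 = 0.2 + \sqrt{0.06}$). The package always computes through
the decomposition and therefore reports $0.21$ for Setting B; it never
hard-codes the quoted $0.2$. The example's qualitative point — identical
(here) or lower expected Brier score despite systematic overestimation — is
unaffected. Similarly, the perfect expectation under a $\mathrm{Unif}(0,1)$
truth is $1/6 \approx 0.1667$, sometimes displayed truncated as $0.16$; the
package uses the exact value.

## What the synthetic generators emulate

True risks are never observable, so all study conditions are synthetic
(`truth_spec()`):

* `constant`, `uniform`, `beta` and `two_point` families cover the
  canonical demonstrations (constant $1/2$; $\mathrm{Unif}(0,1)$;
  $\mathrm{Beta}(1,3)$; the 0-or-1-with-equal-weight distribution whose
  perfect expectation is exactly 0).
* `logistic_model` emulates risks produced by a fitted logistic regression
  on survey data, as used for smoking-status prediction scenarios:
  covariates are i.i.d. standard normal, coefficients are user-set, and
  `nhanes_like_spec()` solves the intercept by quadrature + root finding so
  the induced mean risk hits a target prevalence (default scenario:
  prevalence 0.2, three covariates with coefficients 0.5 — a typical
  adult-smoking prevalence and moderate covariate effects). Only the
  *mechanism* is reproduced: real fitted values from survey data, survey
  weights and covariate correlation are not emulated, so passing tests say
  nothing about the exact levels of any published figure panel — only about
  the qualitative structure (perfect models scoring well above zero, the
  $\bar q - \bar q^2$ bar bounding the perfect expectation).
* `subsample_truth()` mirrors without-replacement subsampling from a pool
  of model-based risks.

Outcomes are generated by `sample_outcomes()` as independent Bernoulli
draws. Predictions derive from the truth through `perturbation_spec()`:
identity (perfect predictions), additive bias $\varepsilon$, independent
$\mathrm{Unif}(-m, m)$ noise, or symmetric Gaussian noise on the log-odds
scale. The logit-scale error law is not fully pinned down by the phrase
"symmetric logit-scale error"; we chose $\delta_i \sim N(0, \sigma)$ on the
logit scale, with degenerate risks $q_i \in \{0, 1\}$ as fixed points
(their log-odds are infinite). For uniform noise the expected Brier excess
over the perfect expectation is $m^2/3$ (the second moment of
$\mathrm{Unif}(-m,m)$), which yields the canonical value
$1/6 + 0.01/3 \approx 0.17$ for a $\mathrm{Unif}(0,1)$ truth with
$m = 0.1$.

### Out-of-range predictions

How noisy predictions falling outside $[0,1]$ were handled in the original
demonstrations is unstated. The default policy clamps to the unit interval
(`clip_to_unit`); a strict `reject` policy that aborts the replicate is
available. Clamping keeps every replicate valid and shifts the
uniform-truth-plus-noise expectation by well under $0.002$, so the
two-decimal value $0.17$ is unaffected; the analytic helper
`analytic_expected_brier()` reports the unclamped expectation and the
engine's Monte-Carlo consistency checks allow for this sub-0.002 shift.

## The simulation design

The engine (`scenario_spec()`, `run_scenario()`) follows an ADEMP-style
design: for each scenario cell — truth distribution, perturbation, sample
size $n \in \{300, 1000\}$, 5000 replicates — it draws $q$, draws outcomes,
derives predictions, and records per replicate the observed Brier score,
the perfect-prediction score on the same outcomes, CIL, the prevalence
reference $\bar y - \bar y^2$, the gap
$\bar y - \bar y^2 - \mathrm{BS}_{\mathrm{perf}}$, and the strict
exceedance flag $\bar y - \bar y^2 > \mathrm{BS}$. Summaries
(`summarize_scenario()`) report the mean, median and 5th/95th percentiles
per metric (type-7 linear-interpolation quantiles, the R default, fixed so
percentiles are reproducible), and the exceedance probability with a
percentile-bootstrap 95% confidence interval obtained by resampling
replicates (1000 resamples by default). Ties count against exceedance:
the event is a strict inequality.

Design choices that were genuinely open:

* **Redrawing the truth.** The truth vector is redrawn i.i.d. in every
  replicate by default (a fully i.i.d. pipeline); `redraw_q = FALSE` fixes
  one draw across replicates, matching the subsample-from-a-fitted-pool
  flavour. With a fixed draw, the scenario's analytic expectation refers to
  the marginal truth distribution while replicates condition on the
  realised $q$, so small systematic gaps between the two are expected.
* **Seeding.** `set.seed(master_seed)` spawns one child seed per replicate
  up front; each replicate runs on its own stream. Identical specifications
  therefore give bit-identical replicate tables, and any execution order
  (including parallel) would reproduce the sequential results.
* **Degenerate inputs.** $n = 1$ is allowed everywhere; the scaled Brier
  score raises a distinct error when $\bar y \in \{0,1\}$ (zero baseline)
  instead of returning an infinity, and the pipeline reports it as
  unavailable while still reporting the remaining metrics.
* **Closed-form identities** are asserted at absolute tolerance $10^{-12}$;
  Monte-Carlo agreement is asserted at four standard errors.

### The exceedance event under constant truth

For a constant truth $q_i \equiv c$ with perfect predictions, algebra gives
$\bar y - \bar y^2 - \mathrm{BS} = -(\bar y - c)^2 \le 0$, so the strict
exceedance probability is exactly zero — the prevalence reference can
never exceed the score. The test suite checks the engine against an exact
binomial enumeration of both this event and its complement: the score
*exceeds* the reference whenever $\bar y \ne c$, which at $n = 300$,
$c = 1/2$ has probability $1 - \binom{300}{150}/2^{300} \approx 0.954$ —
the "score can exceed $\bar y - \bar y^2$ by chance" phenomenon. Scenarios
with non-degenerate truth distributions show both events with positive
probability.

## Problem sizes

The shipped default suite (`default_suite_config()`) uses 5000 replicates
per scenario at $n \in \{300, 1000\}$; `smoke = TRUE` (and the CLI
`--smoke` flag) scales every scenario to 200 replicates for quick runs.
The package's own test suite exercises the engine at 300–1000 replicates
and verifies the uniform-noise scenario at $n = 1000$ with 500 replicates,
sizes at which the Monte-Carlo standard error of the replicate mean is an
order of magnitude below every asserted difference. The strict-properness
oracle exhaustively searches the full prediction grid (step 0.01) for
$n \le 3$.

## Limitations

* Only calibration-in-the-large is implemented; calibration slopes and
  curves, the c-index, net benefit and survival/censoring-weighted scores
  are out of scope.
* The logistic truth emulation reproduces a mechanism, not any real fitted
  model; figure-level numeric replication of survey-based panels is not
  claimed.
* Miscalibration beyond the three perturbation families (e.g. slope
  miscalibration on the logit scale) is not modelled.
* The scaled Brier score is defined against the in-sample prevalence only;
  no external-population baseline is offered, since cross-population
  comparisons are exactly what the score family cannot support.
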