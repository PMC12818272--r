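scenario_for <- function(family, pert = perturbation_spec("identity"),
                         n = 300L, replicates = 300L, seed = 1L, ...) {
  scenario_spec(truth = truth_spec(family, n = n, ...), perturbation = pert,
                n = n, replicates = replicates, master_seed = seed,
                label = paste0(family, "_", pert$kind))
}

test_that("the engine is deterministic given the master seed", {
  spec <- scenario_for("uniform", perturbation_spec("uniform_noise", 0.1),
                       n = 100, replicates = 50, seed = 42)
  t1 <- run_scenario(spec)
  t2 <- run_scenario(spec)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- run_scenario(scenario_spec(spec$truth, spec$perturbation, n = spec$n,
                                   replicates = 50, master_seed = 43,
                                   label = spec$label))
  expect_false(identical(t1$brier, t3$brier))
})

test_that("degenerate and constant truths give the known exact scores", {
  # 0/1 truth with perfect predictions: outcomes equal predictions a.s.
  t2p <- run_scenario(scenario_for("two_point", replicates = 100))
  expect_true(all(t2p$brier == 0))

  # constant q = 1/2 with perfect predictions: BS is exactly 1/4 always
  tc <- run_scenario(scenario_for("constant", n = 1000, replicates = 200,
                                  value = 0.5))
  expect_true(all(tc$brier == 0.25))
  expect_equal(median(tc$brier), 0.25)
})

test_that("replicate means agree with analytic expectations within 4 SE", {
  cases <- list(
    scenario_for("uniform", perturbation_spec("uniform_noise", 0.1),
                 n = 300, replicates = 400, seed = 2),
    scenario_for("beta", n = 300, replicates = 400, seed = 3,
                 shape1 = 1, shape2 = 3),
    scenario_for("uniform", perturbation_spec("additive_bias", 0.1),
                 n = 300, replicates = 400, seed = 4)
  )
  for (spec in cases) {
    tab <- run_scenario(spec)
    expected <- analytic_expected_brier(spec$truth, spec$perturbation)
    se <- sd(tab$brier) / sqrt(nrow(tab))
    # bias/noise terms assume no clamping; allow its < 2e-3 shift on top
    expect_lt(abs(mean(tab$brier) - expected), 4 * se + 2e-3)
  }
})

test_that("score variability shrinks from n = 300 to n = 1000", {
  s300 <- scenario_for("uniform", n = 300, replicates = 400, seed = 5)
  s1000 <- scenario_for("uniform", n = 1000, replicates = 400, seed = 5)
  expect_gt(sd(run_scenario(s300)$brier), sd(run_scenario(s1000)$brier))
})

test_that("fixed-q mode holds one truth vector across replicates", {
  spec <- scenario_spec(truth_spec("uniform", n = 50),
                        n = 50, replicates = 30, master_seed = 9,
                        label = "fixed", redraw_q = FALSE)
  tab <- run_scenario(spec)
  # with q fixed, the perfect expectation is constant, so brier_perfect
  # varies only through the outcomes; its replicate mean approximates it
  expect_equal(nrow(tab), 30L)
  expect_identical(attr(tab, "scenario")$redraw_q, FALSE)
})

test_that("reject policy aborts with the replicate index attached", {
  spec <- scenario_spec(
    truth_spec("uniform", n = 50),
    perturbation_spec("additive_bias", 0.3, "reject"),
    n = 50, replicates = 10, master_seed = 1, label = "rej")
  err <- tryCatch(run_scenario(spec), briersim_reject_error = function(e) e)
  expect_s3_class(err, "briersim_reject_error")
  expect_match(conditionMessage(err), "replicate 1:")
})

test_that("scenario summaries report percentiles, exceedance and references", {
  spec <- scenario_for("constant", n = 300, replicates = 400, seed = 6,
                       value = 0.5)
  tab <- run_scenario(spec)
  summ <- summarize_scenario(tab, bootstrap_reps = 500, seed = 7)
  m <- summ$metrics
  expect_true(all(m$p5 <= m$median & m$median <= m$p95))
  # constant scores: every quantile equals the value
  b <- m[m$metric == "brier", ]
  expect_equal(c(b$median, b$p5, b$p95), rep(0.25, 3))
  expect_equal(summ$truth_reference, 0.25)
  expect_equal(summ$analytic_expected_brier, 0.25)

  # all-exceed table has probability 1 with CI [1, 1]
  tab2 <- tab
  tab2$exceed <- rep(TRUE, nrow(tab2))
  s2 <- summarize_scenario(tab2, bootstrap_reps = 200, seed = 8)
  expect_equal(s2$exceedance$probability, 1)
  expect_equal(c(s2$exceedance$ci_lower, s2$exceedance$ci_upper), c(1, 1))

  expect_error(summarize_scenario(tab, bootstrap_reps = 0),
               class = "briersim_validation_error")
})

test_that("exceedance events match the exact binomial enumeration (constant q)", {
  n <- 300
  oracle <- enumerate_constant_q_events(0.5, n)
  spec <- scenario_for("constant", n = n, replicates = 1000, seed = 10,
                       value = 0.5)
  tab <- run_scenario(spec)
  summ <- summarize_scenario(tab, bootstrap_reps = 500, seed = 11)

  # ybar - ybar^2 - BS = -(ybar - q)^2 <= 0, so strict exceedance is exactly 0
  expect_equal(oracle$p_ref_exceeds_bs, 0)
  expect_equal(summ$exceedance$probability, 0)

  # the complementary event (score exceeds the prevalence reference) is
  # nonzero: P(ybar != q) under Binom(300, 1/2)
  emp <- mean(tab$brier > tab$prevalence_reference)
  se <- sqrt(oracle$p_bs_exceeds_ref * (1 - oracle$p_bs_exceeds_ref) / nrow(tab))
  expect_gt(oracle$p_bs_exceeds_ref, 0)
  expect_lt(abs(emp - oracle$p_bs_exceeds_ref), 4 * se)
})

test_that("epsilon sweep returns exact squared increases and refuses clipping", {
  out <- epsilon_sweep(rep(0.5, 10), c(0, 0.1, 0.2))
  expect_equal(out$expected_increase, c(0, 0.01, 0.04))
  out2 <- epsilon_sweep(c(0.4, 0.6), 0.1, signs = "alternating")
  expect_equal(out2$expected_increase, 0.01)
  expect_error(epsilon_sweep(c(0.05, 0.5), 0.1, signs = "negative"),
               class = "briersim_validation_error")
})

test_that("paired model comparison quantifies chance inversions", {
  spec_a <- scenario_for("constant", n = 1000, replicates = 300, seed = 12,
                         value = 0.5)
  tab_a <- run_scenario(spec_a)
  expect_equal(compare_models(tab_a, tab_a)$ties, 1)

  spec_b <- scenario_spec(truth_spec("constant", n = 1000, value = 0.5),
                          perturbation_spec("additive_bias", 0.1),
                          n = 1000, replicates = 300, master_seed = 12,
                          label = "biased")
  tab_b <- run_scenario(spec_b)
  cmp <- compare_models(tab_a, tab_b)
  # the perfect model has expected advantage 0.01, larger than MC noise
  expect_gt(cmp$win_a, 0.5)
  expect_lt(cmp$mean_difference, 0)

  expect_error(compare_models(tab_a, tab_b[1:10, ]),
               class = "briersim_validation_error")
  spec_c <- scenario_for("uniform", n = 1000, replicates = 300, seed = 12)
  expect_error(compare_models(tab_a, run_scenario(spec_c)),
               class = "briersim_validation_error")
})
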