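# Independent oracles used across the suite.

# Exact event probabilities for constant-q truth with perfect predictions
# p = q: the Brier score is q^2 - 2*q*ybar + ybar with ybar = k/n and
# k ~ Binom(n, q), so every event probability follows from the binomial pmf.
enumerate_constant_q_events <- function(q, n) {
  k <- 0:n
  ybar <- k / n
  bs <- q^2 - 2 * q * ybar + ybar
  pref <- ybar - ybar^2
  pk <- stats::dbinom(k, n, q)
  list(p_ref_exceeds_bs = sum(pk[pref > bs]),
       p_bs_exceeds_ref = sum(pk[bs > pref]))
}

# Brute-force minimiser of the expected Brier score over the full grid of
# prediction vectors with the given step (exhaustive, no structure assumed).
grid_search_minimizer <- function(q, step = 0.01) {
  grid <- seq(0, 1, by = step)
  n <- length(q)
  stopifnot(n <= 3)
  P <- as.matrix(expand.grid(rep(list(grid), n)))
  vals <- rowMeans(sweep(P, 2, q)^2) + mean(q * (1 - q))
  P[which.min(vals), ]
}

# Monte-Carlo estimate of E[BS] at fixed (p, q) by direct Bernoulli draws,
# bypassing the simulation engine. Returns the estimate and its standard
# error across replicates.
mc_expected_brier <- function(p, q, replicates = 5000, seed = 1) {
  set.seed(seed)
  bs <- replicate(replicates, {
    y <- stats::rbinom(length(q), 1, q)
    mean((p - y)^2)
  })
  list(mean = mean(bs), se = stats::sd(bs) / sqrt(replicates), values = bs)
}

random_probability_vector <- function(n) stats::runif(n)
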