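test_that("per-unit outcome probabilities are p, 1-p-q, q and sum to one", {
  expect_equal(multinoulli_pmf(1, p = 0.2, q = 0.1), 0.7)
  expect_equal(multinoulli_pmf(0, p = 0, q = 0), 0)
  for (pq in list(c(0, 0), c(0.3, 0.2), c(0.5, 0.5), c(1, 0))) {
    expect_equal(sum(multinoulli_pmf(0:2, pq[1], pq[2])), 1)
  }
  expect_error(multinoulli_pmf(3, 0.1, 0.1), "outcome")
  expect_error(multinoulli_pmf(1, 0.7, 0.7), "invalid")
})

test_that("repeat-length pmf matches hand-evaluated branch formulas", {
  # no slippage: the reference length is certain
  expect_equal(repeat_length_pmf(7, n = 7, p = 0, q = 0), 1)
  expect_equal(repeat_length_pmf(6, n = 7, p = 0, q = 0), 0)
  # deletion branch: C(2,1) * 0.8 * 0.1
  expect_equal(repeat_length_pmf(1, n = 2, p = 0.1, q = 0.1), 0.16)
  # insertion branch mirrors: C(2,1) * 0.8 * 0.1
  expect_equal(repeat_length_pmf(3, n = 2, p = 0.1, q = 0.1), 0.16)
  # beyond the support
  expect_equal(repeat_length_pmf(5, n = 2, p = 0.1, q = 0.1), 0)
  expect_error(repeat_length_pmf(-1, n = 2, p = 0.1, q = 0.1))
  expect_error(repeat_length_pmf(1, n = 0, p = 0.1, q = 0.1))
})

test_that("total pmf mass equals the closed form (1-q)^n + (1-p)^n - (1-p-q)^n", {
  expect_equal(sum(repeat_length_pmf(0:4, 2, 0.1, 0.1)), 0.98)
  for (n in c(1, 3, 8, 20)) {
    for (p in c(0, 0.05, 0.3)) for (q in c(0, 0.05, 0.3)) {
      mass <- sum(repeat_length_pmf(0:(2 * n), n, p, q))
      expect_equal(mass, (1 - q)^n + (1 - p)^n - (1 - p - q)^n,
                   tolerance = 1e-12)
    }
  }
  # one-sided slippage leaves a complete (binomial) distribution
  expect_equal(sum(repeat_length_pmf(0:20, 10, 0.2, 0)), 1)
  expect_equal(sum(repeat_length_pmf(0:20, 10, 0, 0.2)), 1)
})

test_that("one-sided branches reduce to binomial masses", {
  n <- 9
  for (k in 0:n) {
    expect_equal(repeat_length_pmf(n - k, n, p = 0.13, q = 0),
                 dbinom(k, n, 0.13))
    expect_equal(repeat_length_pmf(n + k, n, p = 0, q = 0.13),
                 dbinom(k, n, 0.13))
  }
})

test_that("log-likelihood is the sum of per-read log pmf terms", {
  expect_equal(log_likelihood(c(2, 2), n = 2, p = 0, q = 0), 0)
  expect_equal(log_likelihood(1, n = 2, p = 0.1, q = 0.1), log(0.16))
  # duplicate read adds exactly one pmf term
  y <- c(4, 5, 7)
  expect_equal(log_likelihood(c(y, 5), n = 5, p = 0.1, q = 0.05),
               log_likelihood(y, n = 5, p = 0.1, q = 0.05) +
                 repeat_length_pmf(5, 5, 0.1, 0.05, log = TRUE))
  # zero-probability observation
  expect_equal(log_likelihood(c(5, 11), n = 5, p = 0.1, q = 0.1), -Inf)
  expect_error(log_likelihood(integer(0), n = 5, p = 0.1, q = 0.1), "m = 0")
})

test_that("closed-form estimator matches direct substitution", {
  e <- estimate_slippage(c(5, 5, 5), n = 5)
  expect_equal(e$p, 0); expect_equal(e$q, 0); expect_equal(e$m, 3)
  e <- estimate_slippage(c(4, 5, 6), n = 5)
  expect_equal(e$p, 1 / 15); expect_equal(e$q, 1 / 15)
  e <- estimate_slippage(c(3, 4), n = 5)
  expect_equal(e$p, 0.3); expect_equal(e$q, 0)
  # named-count representation is equivalent to the expanded multiset
  e2 <- estimate_slippage(c("3" = 1L, "4" = 1L), n = 5)
  expect_equal(e2, e)
  expect_error(estimate_slippage(integer(0), n = 5), "m = 0")
})

test_that("simulation is reproducible and degenerate without slippage", {
  expect_true(all(simulate_allele_distribution(8, 0, 0, 50, seed = 1) == 8))
  a <- simulate_allele_distribution(10, 0.05, 0.01, 200, seed = 42)
  b <- simulate_allele_distribution(10, 0.05, 0.01, 200, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_allele_distribution(10, 0.05, 0.01, 0), "m")
})

test_that("simulated deletion fraction matches the enumerated expectation", {
  n <- 10; p <- 0.05; q <- 0.01; m <- 10000
  y <- simulate_allele_distribution(n, p, q, m, seed = 7)
  obs <- mean(pmax(n - y, 0) / n)
  mu <- expected_del_fraction(n, p, q)
  yy <- 0:(2 * n)
  pr <- repeat_length_pmf(yy, n, p, q); pr <- pr / sum(pr)
  se <- sqrt((sum(pr * (pmax(n - yy, 0) / n)^2) - mu^2) / m)
  expect_lt(abs(obs - mu), 3 * se)
})

test_that("increasing p strictly increases the expected deletion fraction", {
  for (n in c(5, 15)) {
    vals <- vapply(c(0.01, 0.05, 0.1, 0.2), function(p)
      expected_del_fraction(n, p, q = 0.02), numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("likelihood peaks at the closed-form estimates on a lattice", {
  set.seed(31)
  grid <- seq(0, 0.12, by = 0.005)
  for (i in 1:4) {
    p <- runif(1, 0.01, 0.08); q <- runif(1, 0, 0.04)
    y <- simulate_allele_distribution(15, p, q, 5000)
    e <- estimate_slippage(y, 15)
    gm <- slipmsi:::grid_loglik_argmax(y, 15, grid, grid)
    expect_lte(abs(gm$par[["p"]] - e$p), 0.005 + 1e-12)
    expect_lte(abs(gm$par[["q"]] - e$q), 0.005 + 1e-12)
  }
})

test_that("KS fitness accepts self-consistent data and rejects gross misfit", {
  y <- simulate_allele_distribution(12, 0.04, 0.01, 100, seed = 5)
  f <- ks_fitness(y, 12, 0.04, 0.01, seed = 6)
  expect_true(f$fitted)
  # identical samples give statistic 0
  f0 <- ks_fitness(rep(12L, 60), 12, 0, 0, seed = 1)
  expect_equal(f0$statistic, 0)
  expect_true(f0$fitted)
  # all reads at reference length vs p = 0.5: empirical CDFs differ by
  # about the mass below n, far beyond the rejection bound
  f1 <- ks_fitness(rep(20L, 400), 20, 0.5, 0, m_sim = 400, seed = 2)
  expect_false(f1$fitted)
  expect_gt(f1$statistic, 0.9)
})
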