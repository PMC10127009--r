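test_that("variance-ratio F test handles canonical cases", {
  a <- c(1.2, 3.4, -0.5, 2.2, 0.9)
  res <- f_test_variance(a, a)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1)
  set.seed(7)
  x <- rnorm(12); y <- rnorm(9, sd = 2)
  expect_equal(f_test_variance(x, y)$p_value,
               f_test_variance(y, x)$p_value, tolerance = 1e-12)
  # variance ratio 9 with n = 10 each crosses the 1% two-sided bar
  b <- x[1:10]
  res9 <- f_test_variance(3 * b, b)
  expect_equal(res9$statistic, 9, tolerance = 1e-12)
  expect_lt(res9$p_value, 0.01)
  expect_error(f_test_variance(rep(1, 5), rep(2, 5)), "degenerate")
  expect_error(f_test_variance(1, c(1, 2)), "two values")
})

test_that("F test agrees with var.test and an integration-based F CDF oracle", {
  set.seed(21)
  for (i in 1:5) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    ours <- f_test_variance(a, b)
    ref <- var.test(a, b)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # independent oracle: numerically integrate the F density
  f_cdf <- function(q, d1, d2)
    integrate(function(x) df(x, d1, d2), 0, q, rel.tol = 1e-13,
              abs.tol = 1e-15)$value
  grid <- expand.grid(f = c(0.2, 0.7, 1, 1.9, 4.2), d1 = c(3, 9, 19),
                      d2 = c(4, 9, 29))
  for (j in seq_len(nrow(grid))) {
    with(grid[j, ], {
      a <- seq_len(d1 + 1); a <- a * sqrt(f) / sd(a)
      b <- seq_len(d2 + 1); b <- b / sd(b)
      ours <- f_test_variance(a, b)
      lo <- f_cdf(ours$statistic, d1, d2)
      p_oracle <- min(1, 2 * min(lo, 1 - lo))
      expect_equal(ours$p_value, p_oracle, tolerance = 1e-9)
    })
  }
})

test_that("exact Mann-Whitney matches hand enumeration on the worked example", {
  res <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_match(res$method, "exact")
  set.seed(31)
  x <- rnorm(8); y <- rnorm(6)
  expect_equal(mann_whitney_exact(x, y)$p_value,
               mann_whitney_exact(y, x)$p_value, tolerance = 1e-12)
  expect_error(mann_whitney_exact(numeric(0), 1), "empty")
})

test_that("exact path matches brute-force enumeration and wilcox.test", {
  set.seed(41)
  for (i in 1:10) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na); b <- rnorm(nb, mean = runif(1, -1, 1))
    ours <- mann_whitney_exact(a, b)
    expect_equal(ours$p_value, mw_enumerate_p(a, b), tolerance = 1e-12)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(51)
  x <- rnorm(15); y <- rnorm(12, 0.8)
  ours <- mann_whitney_exact(x, y)
  expect_match(ours$method, "approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  xt <- c(1, 2, 2, 3, 5, 5, 5); yt <- c(2, 4, 4, 6)
  ours_t <- mann_whitney_exact(xt, yt)
  ref_t <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE, correct = TRUE))
  expect_equal(ours_t$p_value, ref_t$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_exact(rep(1, 25), rep(1, 25)), "tied")
})

test_that("simulated species speed cohorts differ by the rank test", {
  set.seed(61)
  a <- rnorm(26, 259.3, 15)
  b <- rnorm(26, 207.6, 15)
  res <- mann_whitney_exact(a, b)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$statistic, 26 * 26 / 2)  # first sample stochastically larger
})

test_that("percent_significant reproduces printed-fraction arithmetic", {
  expect_equal(percent_significant(rep(c(TRUE, FALSE), c(36, 23))), 61.0)
  expect_equal(percent_significant(rep(c(TRUE, FALSE), c(12, 9))), 57.1)
  expect_equal(percent_significant(logical(5)), 0)
  expect_error(percent_significant(logical(0)), "no flags")
})

test_that("station significance flags variance differences along the filament", {
  sim <- simulate_sperm(quick_truth(duration = 0.2))
  ser <- collect_series(sim$trace, "tail", 1, 10)
  same <- station_significance(ser, ser)
  expect_equal(sum(same$table$significant), 0)
  expect_equal(same$percent_significant, 0)
  # straight-vs-turn stand-in: 3x amplitude ratio, 10 frames each
  lo <- simulate_sperm(quick_truth(tail_amplitude = 0.05, duration = 0.06,
                                   seed = 8))
  hi <- simulate_sperm(quick_truth(tail_amplitude = 0.15, duration = 0.06,
                                   seed = 9))
  prof <- station_significance(collect_series(hi$trace, "tail", 1, 10),
                               collect_series(lo$trace, "tail", 1, 10),
                               alpha = 0.01)
  expect_gt(mean(prof$table$significant), 0.5)
  # permutation invariance of the summary in station order
  flags <- prof$table$significant
  set.seed(3)
  expect_equal(percent_significant(sample(flags)),
               percent_significant(flags))
})

test_that("type-I error is calibrated at both test levels", {
  # 2000 null replicates per test keep the routine suite quick; the full
  # 10000-replicate calibration at alpha = 0.01 runs in the acceptance suite
  set.seed(71)
  n_rep <- 2000
  pf_ <- pm_ <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(10); y <- rnorm(10)
    pf_[i] <- f_test_variance(x, y)$p_value
    pm_[i] <- mann_whitney_exact(x, y)$p_value
  }
  expect_lt(abs(mean(pf_ < 0.05) - 0.05), 0.05 * 0.3)
  # the rank test is discrete at n = 10 + 10: the attainable level just
  # below 0.05 is P(p < 0.05) = 0.04326 under the exact null
  expect_lt(abs(mean(pm_ < 0.05) - 0.04326), 0.04326 * 0.3)
})
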