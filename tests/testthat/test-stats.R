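test_that("conjugate beta update of the detection probability", {
  p <- beta_posterior(0, 9)
  expect_equal(p$alpha, 1)
  expect_equal(p$beta, 10)
  p0 <- beta_posterior(0, 0)
  expect_equal(c(p0$alpha, p0$beta), c(1, 1)) # no data: the prior
  p3 <- beta_posterior(3, 9)
  expect_equal(c(p3$alpha, p3$beta), c(4, 7))
  expect_error(beta_posterior(10, 9), "detections")
  expect_equal(tidy(p)$mean, 1 / 11)
})

test_that("beta-binomial pmf matches closed forms and numerical integration", {
  post <- beta_posterior(0, 9) # Beta(1, 10)
  expect_equal(beta_binomial_pmf(0, 14, post), 10 / 24, tolerance = 1e-14)

  # uniform-prior predictive is discrete-uniform over k
  unif <- beta_posterior(0, 0)
  expect_equal(beta_binomial_pmf(5, 5, unif), 1 / 6, tolerance = 1e-14)
  expect_equal(beta_binomial_pmf(0:5, 5, unif), rep(1 / 6, 6), tolerance = 1e-14)

  # independent oracle: integrate the binomial likelihood against the
  # posterior density
  oracle <- function(k, n, a, b) {
    stats::integrate(
      function(p) choose(n, k) * p^k * (1 - p)^(n - k) * stats::dbeta(p, a, b),
      0, 1, rel.tol = 1e-12
    )$value
  }
  for (case in list(c(12, 25, 1, 10), c(3, 14, 1, 10), c(7, 20, 4, 7))) {
    post_i <- structure(list(alpha = case[3], beta = case[4]),
                        class = "beta_posterior")
    expect_equal(
      beta_binomial_pmf(case[1], case[2], post_i),
      oracle(case[1], case[2], case[3], case[4]),
      tolerance = 1e-9
    )
  }
})

test_that("beta-binomial pmf normalises and obeys the alpha = 1 closed form", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample.int(200, 1)
    post <- structure(
      list(alpha = runif(1, 0.1, 50), beta = runif(1, 0.1, 50)),
      class = "beta_posterior"
    )
    expect_equal(sum(beta_binomial_pmf(0:n, n, post)), 1, tolerance = 1e-12)
  }
  for (beta in c(1, 2, 10, 37)) {
    for (n in c(1, 14, 100)) {
      post <- structure(list(alpha = 1, beta = beta), class = "beta_posterior")
      expect_equal(beta_binomial_pmf(0, n, post), beta / (beta + n),
                   tolerance = 1e-13)
    }
  }
})

test_that("beta-binomial tail complements the cdf and handles endpoints", {
  post <- beta_posterior(0, 9)
  expect_equal(beta_binomial_sf(0, 25, post), 1)
  unif <- beta_posterior(0, 0)
  expect_equal(beta_binomial_sf(5, 5, unif), 1 / 6, tolerance = 1e-14)
  for (k in 1:10) {
    cdf <- sum(beta_binomial_pmf(0:(k - 1), 10, post))
    expect_equal(beta_binomial_sf(k, 10, post) + cdf, 1, tolerance = 1e-12)
  }
})

test_that("predictive fold change is the baseline/treatment probability ratio", {
  expect_equal(predictive_fold_change(0.4, 0.4), 1)
  expect_equal(predictive_fold_change(0.4, 0.004), 100)
  expect_error(predictive_fold_change(0.4, 0), "positive")
  res <- detection_predictive_test(0, 9, 0, 14, 12, 25)
  expect_equal(res$posterior_beta, 10)
  expect_equal(res$p_baseline, 10 / 24, tolerance = 1e-14)
  expect_equal(res$fold_change_pmf,
               res$p_baseline / res$p_treatment_pmf, tolerance = 1e-12)
})

test_that("exact fair-coin binomial tails match a Pascal-triangle oracle", {
  expect_identical(binomial_tail_lower(3, 15, 0.5), 576 / 32768)
  expect_identical(binomial_tail_lower(3, 15, 0.5), 0.017578125)
  expect_equal(binomial_tail_lower(15, 15, 0.5), 1)
  expect_equal(binomial_tail_lower(0, 4, 0.5), 1 / 16)

  # oracle: build Pascal's triangle by integer addition (exact in doubles for
  # n <= 30) and take cumulative sums over 2^n
  for (n in c(1, 5, 10, 15, 22, 30)) {
    row <- 1
    for (i in seq_len(n)) row <- c(0, row) + c(row, 0)
    tails <- cumsum(row) / 2^n
    for (k in c(0, floor(n / 2), n)) {
      expect_identical(binomial_tail_lower(k, n, 0.5), tails[k + 1])
    }
  }
  # general p agrees with the distribution function
  expect_equal(binomial_tail_lower(3, 15, 0.3), stats::pbinom(3, 15, 0.3))
})

test_that("Pearson test reports r, t on n-2 df and a Fisher-Z interval", {
  perfect <- pearson_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(perfect$estimate, 1)
  anti <- pearson_test(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(anti$estimate, -1)
  expect_equal(anti$conf.low, anti$estimate) # degenerate interval at |r| = 1

  set.seed(13)
  x <- rnorm(20)
  y <- 0.6 * x + rnorm(20)
  res <- pearson_test(x, y)
  r <- cor(x, y)
  n <- 20
  expect_equal(res$estimate, r, tolerance = 1e-12)
  expect_equal(res$df, n - 2L)
  # manual formulas as the oracle
  t_manual <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$statistic, t_manual, tolerance = 1e-9)
  expect_equal(res$p.value, 2 * stats::pt(-abs(t_manual), n - 2),
               tolerance = 1e-12)
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
  expect_equal(c(res$conf.low, res$conf.high), ci, tolerance = 1e-9)
  expect_error(pearson_test(x, rep(1, 20)), "constant")
})

test_that("linear-log regression recovers a noise-free line and enforces positivity", {
  burden <- c(0.01, 0.1, 1, 10) # percents; logs -2, -1, 0, 1
  df <- data.frame(
    burden_pct = burden,
    ct_change_percent = 10 + 30 * log10(burden)
  )
  fit <- burden_regression(df)
  expect_equal(fit$slope, 30, tolerance = 1e-9)
  expect_equal(fit$intercept, 10, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$significant)

  flat <- data.frame(burden_pct = burden, ct_change_percent = 5)
  fit_flat <- burden_regression(flat)
  expect_equal(fit_flat$slope, 0, tolerance = 1e-12)
  expect_equal(fit_flat$r_squared, 0, tolerance = 1e-12)

  bad <- data.frame(burden_pct = c(0, 1, 2), ct_change_percent = 1:3)
  expect_error(burden_regression(bad), "detected samples")
})

test_that("regression F equals the squared slope t and r^2 the squared Pearson r", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    burden <- 10^runif(n, -1, 1.5)
    ct <- 10 + 30 * log10(burden) + rnorm(n, 0, 10)
    df <- data.frame(burden_pct = burden, ct_change_percent = ct)
    fit <- burden_regression(df)
    expect_equal(fit$f_stat, fit$slope_t^2, tolerance = 1e-9)
    r <- cor(log10(burden), ct)
    expect_equal(fit$r_squared, r^2, tolerance = 1e-9)
    # Pearson test on the same pairs lands at approximately the same p value
    expect_equal(pearson_test(log10(burden), ct)$p.value, fit$slope_p,
                 tolerance = 1e-9)
    # OLS slope relation to r
    expect_equal(fit$slope, r * sd(ct) / sd(log10(burden)), tolerance = 1e-9)
  }
})

test_that("two-sample t test reports group summaries and sensible extremes", {
  same <- two_sample_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  far <- two_sample_t(rnorm(10, 1000, 0.1), rnorm(10, 0, 0.1))
  expect_lt(far$p.value, 1e-6)
  expect_equal(far$mean_a, 1000, tolerance = 0.5)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("Welch p values agree with a permutation oracle on small groups", {
  set.seed(47)
  a <- rnorm(8, 0.6)
  b <- rnorm(8, 0)
  p_welch <- two_sample_t(a, b)$p.value
  pooled <- c(a, b)
  obs <- abs(stats::t.test(a, b)$statistic)
  perm <- replicate(4000, {
    idx <- sample(16, 8)
    abs(stats::t.test(pooled[idx], pooled[-idx])$statistic)
  })
  p_perm <- mean(perm >= obs)
  expect_equal(p_welch, p_perm, tolerance = 0.05)
})

test_that("delta-delta-Ct copy numbers follow the diploid-calibrator rule", {
  # sample delta Ct equal to the calibrator: diploid, not amplified
  same <- mdm2_copy_number(c(25, 25, 25), c(27, 27, 27), calibrator_delta_ct = -2)
  expect_equal(same$copy_number, 2)
  expect_false(same$amplified)
  # ddCt = -2 doubles twice: 8 copies, amplified
  amp <- mdm2_copy_number(c(23, 23, 23), c(27, 27, 27), calibrator_delta_ct = -2)
  expect_equal(amp$delta_delta_ct, -2)
  expect_equal(amp$copy_number, 8)
  expect_true(amp$amplified)
  # ddCt = -1.25 gives ~4.76 copies: below the strict > 5 rule
  near <- mdm2_copy_number(c(24.75, 24.75, 24.75), c(27, 27, 27),
                           calibrator_delta_ct = -1)
  expect_equal(near$copy_number, 2 * 2^1.25, tolerance = 1e-12)
  expect_false(near$amplified)
  expect_warning(mdm2_copy_number(c(25, 25), c(27, 27, 27), -2), "replicates")
  expect_error(mdm2_copy_number(numeric(0), c(27, 27, 27), -2), "non-empty")
})
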