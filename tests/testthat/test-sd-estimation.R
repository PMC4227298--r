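test_that("pooled SD is the root mean of the two arm variances", {
  expect_equal(pooled_sd(1, 1), 1)
  expect_equal(pooled_sd(0.64, 0.36), sqrt(0.5))
  expect_equal(pooled_sd(0, 0), 0)
  expect_equal(pooled_sd(c(1, 0.64), c(1, 0.36)), c(1, sqrt(0.5)))
  expect_error(pooled_sd(-0.1, 1), "s1_sq")
})

test_that("pooled-SD standard error follows sd / sqrt(2 df)", {
  expect_equal(se_pooled_sd(1, 18), 1 / 6)
  expect_equal(se_pooled_sd(0, 18), 0)
  expect_equal(se_pooled_sd(1, 68), 1 / sqrt(136))
  expect_error(se_pooled_sd(1, 0), "df")
})

test_that("pilot_sd_estimates applies the 2(n-1) pooling convention", {
  reps <- data.frame(n_per_group = 10L, s1_sq = c(1, 0.64),
                     s2_sq = c(1, 0.36))
  est <- pilot_sd_estimates(reps)
  expect_equal(est$df, c(18L, 18L))
  expect_equal(est$sd_p, c(1, sqrt(0.5)))
  expect_equal(est$se_sd_p, est$sd_p / sqrt(36))
  expect_error(pilot_sd_estimates(data.frame(x = 1)), "columns")
})

test_that("chi-square SD limits match the quantile transformation", {
  # frozen from qchisq(0.975, 18) = 31.52638, qchisq(0.025, 18) = 8.230746
  ci <- sd_confidence_limits(1, 18, 0.95)
  expect_equal(ci$lower, 0.755613, tolerance = 1e-6)
  expect_equal(ci$upper, 1.478825, tolerance = 1e-6)
  expect_equal(ci$width, ci$upper - ci$lower)
  expect_true(ci$lower <= 1 && 1 <= ci$upper)

  zero <- sd_confidence_limits(0, 18)
  expect_equal(c(zero$lower, zero$upper, zero$width), c(0, 0, 0))

  # width strictly decreases in df at fixed sd_p
  w <- sd_confidence_limits(1, c(18L, 68L, 78L))$width
  expect_true(all(diff(w) < 0))
  expect_error(sd_confidence_limits(1, 18, level = 1.2), "level")
})

test_that("closed-form E[SD_p] matches numerical integration of the chi law", {
  for (df in c(8L, 18L, 58L, 68L)) {
    expect_equal(expected_pooled_sd(df), integrate_expected_sd(df),
                 tolerance = 1e-8)
  }
  expect_equal(expected_pooled_sd(18, true_sd = 3),
               3 * expected_pooled_sd(18))
  # consistency: bias vanishes as df grows
  expect_lt(abs(expected_pooled_sd(5000) - 1), 1e-4)
})

test_that("Monte-Carlo mean interval width agrees with its closed form", {
  for (n in c(10L, 35L)) {
    df <- 2L * (n - 1L)
    w_mc <- mean_sd_ci_width(n, n_reps = 20000, seed = 61)
    w_exact <- expected_sd_ci_width(df)
    # width = sd_p * const, so SE(mean width) = const * sd(SD_p) / sqrt(N)
    const <- w_exact / expected_pooled_sd(df)
    se <- const * sqrt(1 - expected_pooled_sd(df)^2) / sqrt(20000)
    expect_lt(abs(w_mc - w_exact), 4 * se)
  }
})

test_that("precision gain is the percent width reduction", {
  expect_equal(precision_gain(2, 2), 0)
  expect_equal(precision_gain(2, 1), 50)
  expect_equal(precision_gain(expected_sd_ci_width(68),
                              expected_sd_ci_width(78)),
               6.903726, tolerance = 1e-6)
  expect_error(precision_gain(0, 1), "undefined gain")
})

test_that("SD bias is the signed mean error, matching the Gamma closed form", {
  expect_equal(sd_bias(rep(1, 10), 1), 0)
  expect_error(sd_bias(numeric(0)), "no SD estimates")

  # total size 20 (df 18): E[SD_p] - 1 = -0.0137859
  expect_equal(expected_pooled_sd(18) - 1, -0.0137859, tolerance = 1e-4)
  est <- pilot_sd_estimates(simulate_normal_pilot(10, 200000, seed = 62))
  se <- sqrt(1 - expected_pooled_sd(18)^2) / sqrt(200000)
  expect_lt(abs(sd_bias(est) - (expected_pooled_sd(18) - 1)), 3 * se)
})

test_that("inflation factor is the one-sided chi-square upper-limit multiplier", {
  # frozen from qchisq(0.2, 18) = 12.85680, qchisq(0.5, 18) = 17.33790
  expect_equal(inflation_factor(18, 0.8), 1.183225, tolerance = 1e-6)
  expect_equal(inflation_factor(18, 0.5), 1.018915, tolerance = 1e-6)
  expect_gt(inflation_factor(18, 0.8), 1)
  expect_lt(abs(inflation_factor(20000L, 0.8) - 1), 0.01)
  expect_error(inflation_factor(18, 0.4), "confidence")
  expect_error(inflation_factor(18, 1), "confidence")

  # multiplying SD_p by it gives the upper one-sided confidence limit:
  # P(sd_p * IF >= sigma) = P(chisq_df >= df / IF^2) = confidence
  f <- inflation_factor(28, 0.8)
  expect_equal(pchisq(28 / f^2, 28, lower.tail = FALSE), 0.8,
               tolerance = 1e-10)
})

test_that("SD machinery is scale equivariant", {
  reps <- simulate_normal_pilot(15, 200, seed = 63)
  est <- pilot_sd_estimates(reps)
  k <- 2.5
  scaled <- reps
  scaled$s1_sq <- reps$s1_sq * k^2
  scaled$s2_sq <- reps$s2_sq * k^2
  est_k <- pilot_sd_estimates(scaled)
  expect_equal(est_k$sd_p, k * est$sd_p)
  expect_equal(est_k$se_sd_p, k * est$se_sd_p)
  ci <- sd_confidence_limits(est$sd_p, est$df)
  ci_k <- sd_confidence_limits(est_k$sd_p, est_k$df)
  expect_equal(ci_k$lower, k * ci$lower)
  expect_equal(ci_k$width, k * ci$width)
  # gain and inflation factor are scale free
  expect_equal(precision_gain(k * 2, k * 1.5), precision_gain(2, 1.5))
  expect_equal(expected_sd_ci_width(18, true_sd = k),
               k * expected_sd_ci_width(18))
})

test_that("the chi-square SD interval covers the true SD at its nominal rate", {
  est <- pilot_sd_estimates(simulate_normal_pilot(10, 10000, seed = 64))
  ci <- sd_confidence_limits(est$sd_p, est$df, 0.95)
  cover <- mean(ci$lower <= 1 & 1 <= ci$upper)
  expect_lt(abs(cover - 0.95), 4 * sqrt(0.95 * 0.05 / 10000))
})
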