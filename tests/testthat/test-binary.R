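test_that("Wilson interval matches the textbook score formula", {
  iv <- wilson_interval(30, 60)
  expect_equal(iv$lower, 0.3773502, tolerance = 1e-6)
  expect_equal(iv$upper, 0.6226498, tolerance = 1e-6)
  expect_equal(iv$width, 0.2452996, tolerance = 1e-6)

  # against the one-at-a-time oracle on assorted cases
  for (case in list(c(3, 10), c(0, 10), c(10, 10), c(17, 45), c(120, 200))) {
    got <- wilson_interval(case[1], case[2])
    want <- wilson_oracle(case[1], case[2])
    expect_equal(got$lower, max(0, want["lower"]), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got$upper, min(1, want["upper"]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("Wilson interval respects [0,1] and its boundary and symmetry structure", {
  zero <- wilson_interval(0, 10)
  expect_identical(zero$lower, 0)
  expect_equal(zero$upper, 0.2775328, tolerance = 1e-6)
  full <- wilson_interval(10, 10)
  expect_identical(full$upper, 1)
  expect_equal(full$lower, 1 - zero$upper)

  # symmetric about one half at y = n/2, and under y <-> n - y
  mid <- wilson_interval(20, 40)
  expect_equal(mid$lower + mid$upper, 1)
  a <- wilson_interval(7, 30)
  b <- wilson_interval(23, 30)
  expect_equal(a$lower, 1 - b$upper)
  expect_equal(a$width, b$width)

  all_iv <- wilson_interval(0:50, 50)
  expect_true(all(all_iv$lower >= 0 & all_iv$upper <= 1))
  expect_true(all(all_iv$lower <= all_iv$theta_hat &
                    all_iv$theta_hat <= all_iv$upper))
  expect_error(wilson_interval(11, 10), "y")
  expect_error(wilson_interval(-1, 10), "y")
})

test_that("binomial enumeration reproduces direct summation oracles", {
  expect_equal(enumerate_binomial_expectation(0.5, 1, "theta_hat"), 0.5)
  expect_equal(enumerate_binomial_expectation(0.5, 60, "theta_hat"), 0.5)

  mo <- width_moments_oracle(0.3, 20)
  expect_equal(enumerate_binomial_expectation(0.3, 20, "width"),
               unname(mo["mean"]), tolerance = 1e-12)
  # coverage by explicit summation over covering outcomes
  cov_direct <- sum(dbinom(0:50, 50, 0.1) *
                      vapply(0:50, function(y) {
                        iv <- wilson_oracle(y, 50)
                        as.numeric(iv["lower"] <= 0.1 & 0.1 <= iv["upper"])
                      }, numeric(1)))
  expect_equal(enumerate_binomial_expectation(0.1, 50, "coverage"),
               cov_direct, tolerance = 1e-12)
  expect_error(enumerate_binomial_expectation(0.3, 20, "median"),
               "should be one of")
})

test_that("Monte-Carlo cell summaries converge to their enumeration twins", {
  for (cell in list(c(0.3, 20), c(0.1, 50), c(0.5, 25), c(0.45, 105))) {
    th <- cell[1]; n <- cell[2]
    reps <- 30000
    mc <- summarize_binomial_cell(th, n, method = "simulate", n_reps = reps,
                                  seed = 81)
    ex <- summarize_binomial_cell(th, n, method = "enumerate")
    mo <- width_moments_oracle(th, n)
    expect_lt(abs(mc$mean_theta_hat - ex$mean_theta_hat),
              4 * sqrt(th * (1 - th) / n / reps))
    expect_lt(abs(mc$mean_width - ex$mean_width),
              4 * mo["sd"] / sqrt(reps) + 1e-12)
    expect_lt(abs(mc$coverage - ex$coverage),
              4 * sqrt(ex$coverage * (1 - ex$coverage) / reps))
  }
})

test_that("enumeration summaries have the symmetry and worst-case structure", {
  # exact zero bias at one half
  even <- summarize_binomial_cell(0.5, 60, method = "enumerate")
  expect_equal(even$bias, 0, tolerance = 1e-12)
  odd <- summarize_binomial_cell(0.5, 25, method = "enumerate")
  expect_equal(odd$bias, 0, tolerance = 1e-12)

  for (n in c(25L, 60L, 100L)) {
    for (th in c(0.1, 0.25, 0.4)) {
      expect_equal(enumerate_binomial_expectation(th, n, "width"),
                   enumerate_binomial_expectation(1 - th, n, "width"),
                   tolerance = 1e-12)
    }
    # width maximal at one half over the study grid
    grid <- seq(0.10, 0.50, by = 0.05)
    w <- vapply(grid, enumerate_binomial_expectation, numeric(1),
                n = n, quantity = "width")
    expect_equal(which.max(w), length(grid))
  }
})

test_that("score-interval coverage stays near nominal across the study grid", {
  for (th in seq(0.10, 0.50, by = 0.05)) {
    for (n in c(10L, 45L, 100L, 200L)) {
      cov <- enumerate_binomial_expectation(th, n, "coverage")
      expect_gte(cov, 0.90)
      expect_lte(cov, 0.99)
    }
  }
})

test_that("binary precision table carries exact gains with the expected trend", {
  tab <- binary_precision_table(thetas = c(0.1, 0.5),
                                sizes = seq(10L, 110L, by = 5L),
                                method = "enumerate")
  expect_equal(nrow(tab), 2 * 21)
  expect_true(all(is.na(tab$gain_next[tab$n == 110])))
  done <- tab[!is.na(tab$gain_next), ]
  expect_true(all(done$gain_next > 0))
  # decreasing trend in n: compare early vs late grid averages
  for (th in c(0.1, 0.5)) {
    g <- done$gain_next[done$theta_true == th]
    expect_gt(mean(g[1:5]), mean(g[(length(g) - 4):length(g)]))
  }
  # gain thresholds from the exact widths
  g60 <- done$gain_next[done$n == 60]
  expect_true(all(g60 < 5))
  g100 <- done$gain_next[done$n == 100]
  expect_true(all(g100 <= 3))
})

test_that("simulated binary table is seed-reproducible", {
  a <- binary_precision_table(thetas = 0.3, sizes = c(10L, 15L),
                              method = "simulate", min_reps = 2000L,
                              se_target = 0.01, seed = 7)
  b <- binary_precision_table(thetas = 0.3, sizes = c(10L, 15L),
                              method = "simulate", min_reps = 2000L,
                              se_target = 0.01, seed = 7)
  expect_identical(a, b)
  expect_equal(unique(a$n_reps), 2100L)  # ceiling(0.21/1e-4) = 2100
})
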