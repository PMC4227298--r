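# Independent oracles used across test files.

# Expected SD_p by numerical integration of the chi distribution, kept
# independent of the package's lgamma-based closed form.
integrate_expected_sd <- function(df, true_sd = 1) {
  # sd_p = true_sd * sqrt(x / df), x ~ chisq(df)
  f <- function(x) true_sd * sqrt(x / df) * dchisq(x, df)
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# Brute-force Wilson interval written from the textbook formula, one (y, n)
# at a time, as the oracle for the vectorised implementation.
wilson_oracle <- function(y, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- y / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = centre - half, upper = centre + half)
}

# Exact mean/SD of the Wilson width under Binomial(n, theta), by direct
# summation with the oracle interval (not the package's enumeration).
width_moments_oracle <- function(theta, n, level = 0.95) {
  w <- vapply(0:n, function(y) {
    iv <- wilson_oracle(y, n, level)
    unname(iv["upper"] - iv["lower"])
  }, numeric(1))
  pr <- dbinom(0:n, n, theta)
  m <- sum(pr * w)
  c(mean = m, sd = sqrt(sum(pr * (w - m)^2)))
}
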