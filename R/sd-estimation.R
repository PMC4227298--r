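#' Pooled standard deviation of two balanced arms
#'
#' For a balanced two-arm design the pooled variance is the arithmetic mean
#' of the two arms' unbiased sample variances, and the pooled SD is its
#' square root: `SD_p = sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param s1_sq,s2_sq Sample variances (n - 1 denominator) of the two arms;
#'   vectors are paired elementwise.
#' @return Numeric vector of pooled SDs.
#' @examples
#' pooled_sd(0.64, 0.36)  # sqrt(0.5)
#' @export
pooled_sd <- function(s1_sq, s2_sq) {
  check_number(s1_sq, "s1_sq", lower = 0, allow_vector = TRUE)
  check_number(s2_sq, "s2_sq", lower = 0, allow_vector = TRUE)
  sqrt((s1_sq + s2_sq) / 2)
}

#' Reduce simulated pilot replicates to pooled-SD estimates
#'
#' Turns the variance pairs from [simulate_normal_pilot()] into one pooled-SD
#' estimate per replicate, with its degrees of freedom `df = 2 * (n - 1)`
#' (one arm of `n` contributes `n - 1`) and large-sample standard error.
#'
#' @param replicates Data frame with columns `n_per_group`, `s1_sq`, `s2_sq`.
#' @return Data frame with columns `n_per_group`, `df`, `sd_p`, `se_sd_p`.
#' @export
pilot_sd_estimates <- function(replicates) {
  needed <- c("n_per_group", "s1_sq", "s2_sq")
  if (!is.data.frame(replicates) || !all(needed %in% names(replicates))) {
    stop_invalid("invalid input: `replicates` must have columns ",
                 paste(needed, collapse = ", "))
  }
  df <- 2L * (as.integer(replicates$n_per_group) - 1L)
  sd_p <- pooled_sd(replicates$s1_sq, replicates$s2_sq)
  data.frame(n_per_group = replicates$n_per_group,
             df = df,
             sd_p = sd_p,
             se_sd_p = se_pooled_sd(sd_p, df))
}

#' Large-sample standard error of a pooled SD
#'
#' `se(SD_p) = SD_p / sqrt(2 * df)`, the delta-method standard error of a
#' standard deviation estimated with `df` degrees of freedom.
#'
#' @param sd_p Pooled SD estimate(s).
#' @param df Degrees of freedom, `2 * (n - 1)` for two balanced arms of `n`.
#' @return Numeric vector of standard errors.
#' @examples
#' se_pooled_sd(1, 18)  # 1/6
#' @export
se_pooled_sd <- function(sd_p, df) {
  check_number(sd_p, "sd_p", lower = 0, allow_vector = TRUE)
  check_count(df, "df", allow_vector = TRUE)
  sd_p / sqrt(2 * df)
}

#' Chi-square confidence limits for a standard deviation
#'
#' Since `df * SD_p^2 / sigma^2` is chi-square distributed with `df` degrees
#' of freedom, the equal-tailed interval for the true SD is
#' `SD_p * sqrt(df / q_hi)` to `SD_p * sqrt(df / q_lo)`, with `q_lo` and
#' `q_hi` the lower-tail chi-square quantiles at `(1 - level)/2` and
#' `1 - (1 - level)/2`.
#'
#' @param sd_p Pooled SD estimate(s).
#' @param df Degrees of freedom of the estimate.
#' @param level Confidence level in (0, 1).
#' @return Data frame with columns `sd_p`, `df`, `lower`, `upper`, `level`,
#'   `width`.
#' @examples
#' sd_confidence_limits(1, df = 18)
#' @export
sd_confidence_limits <- function(sd_p, df, level = 0.95) {
  check_number(sd_p, "sd_p", lower = 0, allow_vector = TRUE)
  check_count(df, "df", allow_vector = TRUE)
  check_number(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  q_lo <- stats::qchisq((1 - level) / 2, df)
  q_hi <- stats::qchisq(1 - (1 - level) / 2, df)
  lower <- sd_p * sqrt(df / q_hi)
  upper <- sd_p * sqrt(df / q_lo)
  data.frame(sd_p = sd_p, df = df, lower = lower, upper = upper,
             level = level, width = upper - lower)
}

#' Expected value of the pooled SD under normality
#'
#' The pooled SD underestimates the true SD in small samples:
#' `E[SD_p] = c(df) * sigma` with
#' `c(df) = sqrt(2/df) * Gamma((df + 1)/2) / Gamma(df/2)`, which rises to 1
#' as `df` grows. This closed form is the deterministic oracle for the
#' simulated bias and mean interval width.
#'
#' @param df Degrees of freedom (vectorised).
#' @param true_sd True standard deviation.
#' @return `E[SD_p]` for each `df`.
#' @examples
#' expected_pooled_sd(18) - 1  # small-sample bias at total size 20
#' @export
expected_pooled_sd <- function(df, true_sd = 1) {
  check_count(df, "df", allow_vector = TRUE)
  check_number(true_sd, "true_sd", lower = 0, strict_lower = TRUE)
  true_sd * sqrt(2 / df) * exp(lgamma((df + 1) / 2) - lgamma(df / 2))
}

#' Expected width of the chi-square confidence interval for the SD
#'
#' The interval of [sd_confidence_limits()] scales linearly in `SD_p`, so its
#' expected width is `E[SD_p] * (sqrt(df/q_lo) - sqrt(df/q_hi))` with
#' `E[SD_p]` from [expected_pooled_sd()]. Used as the closed-form twin of the
#' Monte-Carlo mean width.
#'
#' @inheritParams expected_pooled_sd
#' @param level Confidence level.
#' @return Expected interval width for each `df`.
#' @export
expected_sd_ci_width <- function(df, level = 0.95, true_sd = 1) {
  check_count(df, "df", allow_vector = TRUE)
  check_number(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  q_lo <- stats::qchisq((1 - level) / 2, df)
  q_hi <- stats::qchisq(1 - (1 - level) / 2, df)
  expected_pooled_sd(df, true_sd) * (sqrt(df / q_lo) - sqrt(df / q_hi))
}

#' Monte-Carlo mean confidence-interval width for the pooled SD
#'
#' Simulates pilot trials of `n_per_group` per arm and averages the width of
#' the chi-square SD interval across replicates. Converges to
#' [expected_sd_ci_width()] at `df = 2 * (n_per_group - 1)`.
#'
#' @inheritParams simulate_normal_pilot
#' @param level Confidence level.
#' @return A single number, the mean interval width.
#' @export
mean_sd_ci_width <- function(n_per_group, level = 0.95, n_reps = 10000L,
                             true_mean = 0, true_sd = 1, seed = NULL) {
  reps <- simulate_normal_pilot(n_per_group, n_reps, true_mean, true_sd, seed)
  est <- pilot_sd_estimates(reps)
  mean(sd_confidence_limits(est$sd_p, est$df, level)$width)
}

#' Relative precision gain from enlarging a pilot
#'
#' The percentage reduction in mean confidence-interval width when the pilot
#' grows by one grid step: `100 * (W_n - W_bigger) / W_n`. Applies unchanged
#' to the continuous outcome (five subjects added per group) and the binary
#' outcome (five subjects added to the single arm).
#'
#' @param width Mean CI width at the smaller size (vectorised).
#' @param width_bigger Mean CI width at the enlarged size.
#' @return Percentage gain; positive whenever the width shrinks.
#' @examples
#' precision_gain(expected_sd_ci_width(68), expected_sd_ci_width(78))
#' @export
precision_gain <- function(width, width_bigger) {
  check_number(width, "width", lower = 0, allow_vector = TRUE)
  check_number(width_bigger, "width_bigger", lower = 0, allow_vector = TRUE)
  if (any(width == 0)) {
    stop_invalid("undefined gain: baseline `width` must be positive")
  }
  100 * (width - width_bigger) / width
}

#' Signed bias of a set of SD estimates
#'
#' Mean of (estimate minus truth); negative values mean the pilot tends to
#' underestimate the true SD.
#'
#' @param sd_p Vector of pooled-SD estimates (or a data frame with an `sd_p`
#'   column, as returned by [pilot_sd_estimates()]).
#' @param true_sd True standard deviation.
#' @return The signed mean error.
#' @export
sd_bias <- function(sd_p, true_sd = 1) {
  if (is.data.frame(sd_p)) sd_p <- sd_p$sd_p
  check_number(sd_p, "sd_p", lower = 0, allow_vector = TRUE)
  if (length(sd_p) == 0) {
    stop_invalid("invalid input: no SD estimates supplied")
  }
  check_number(true_sd, "true_sd", lower = 0, strict_lower = TRUE)
  mean(sd_p) - true_sd
}

#' Confidence-based inflation factor for a pilot SD estimate
#'
#' Multiplying `SD_p` by `sqrt(df / q)`, with `q` the lower-tail chi-square
#' quantile at probability `1 - confidence`, gives the upper one-sided
#' confidence limit of the true SD at the stated confidence (Browne's
#' adjustment). Planning the definitive trial with the inflated SD then
#' attains the target power with at least that confidence. At
#' `confidence = 0.5` the factor is a median-bias correction only.
#'
#' @param df Degrees of freedom of the pilot SD estimate (vectorised).
#' @param confidence One-sided confidence level in [0.5, 1); values below
#'   0.5 would deflate the estimate and are rejected.
#' @return Inflation factor(s), each > 1 for `confidence > 0.5`.
#' @examples
#' inflation_factor(18, 0.8)
#' @export
inflation_factor <- function(df, confidence = 0.8) {
  check_count(df, "df", allow_vector = TRUE)
  check_number(confidence, "confidence", lower = 0.5, upper = 1,
               strict_upper = TRUE)
  sqrt(df / stats::qchisq(1 - confidence, df))
}
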