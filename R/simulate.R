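#' Simulate balanced two-arm normal pilot trials
#'
#' Draws `n_reps` independent pilot trials, each with two arms of
#' `n_per_group` normally distributed outcomes, and reduces every trial to
#' the two unbiased (n - 1 denominator) sample variances. These are the
#' sufficient statistics for everything downstream: the pooled SD, its
#' confidence limits, and the sample-size plans derived from it.
#'
#' @param n_per_group Subjects per arm; at least 2 so each arm contributes a
#'   degree of freedom to the pooled variance.
#' @param n_reps Number of simulated pilot trials.
#' @param true_mean,true_sd True mean and standard deviation of the outcome,
#'   common to both arms.
#' @param seed Optional integer seed; identical seed and parameters reproduce
#'   the replicates exactly. The caller's RNG state is left untouched.
#' @param keep_outcomes If `TRUE`, attach the raw outcome matrices as
#'   attributes `"arm1"` and `"arm2"` (rows = subjects, columns = replicates)
#'   for debugging; only the variances are needed for the analysis.
#' @return A data frame with one row per replicate and columns `replicate`,
#'   `n_per_group`, `s1_sq`, `s2_sq`.
#' @examples
#' reps <- simulate_normal_pilot(10, n_reps = 5, seed = 1)
#' pilot_sd_estimates(reps)
#' @export
simulate_normal_pilot <- function(n_per_group, n_reps,
                                  true_mean = 0, true_sd = 1,
                                  seed = NULL, keep_outcomes = FALSE) {
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 2L)
  n_reps <- check_count(n_reps, "n_reps")
  check_number(true_mean, "true_mean")
  check_number(true_sd, "true_sd", lower = 0, strict_lower = TRUE)

  draw_arm <- function() {
    matrix(stats::rnorm(n_per_group * n_reps, mean = true_mean, sd = true_sd),
           nrow = n_per_group, ncol = n_reps)
  }
  col_var <- function(x) {
    m <- colMeans(x)
    (colSums(x * x) - n_per_group * m * m) / (n_per_group - 1)
  }
  with_seed(seed, {
    # draw in blocks so a 10^6-replicate run never holds >~100 MB of outcomes
    block <- max(1L, min(n_reps, as.integer(250000 / max(1, n_per_group / 30))))
    starts <- seq(1L, n_reps, by = block)
    s1 <- s2 <- numeric(n_reps)
    arm1 <- arm2 <- NULL
    for (st in starts) {
      idx <- st:min(st + block - 1L, n_reps)
      n_reps_block <- length(idx)
      x1 <- matrix(stats::rnorm(n_per_group * n_reps_block, true_mean, true_sd),
                   nrow = n_per_group)
      x2 <- matrix(stats::rnorm(n_per_group * n_reps_block, true_mean, true_sd),
                   nrow = n_per_group)
      s1[idx] <- col_var(x1)
      s2[idx] <- col_var(x2)
      if (keep_outcomes) {
        arm1 <- cbind(arm1, x1)
        arm2 <- cbind(arm2, x2)
      }
    }
    out <- data.frame(replicate = seq_len(n_reps),
                      n_per_group = n_per_group,
                      s1_sq = s1, s2_sq = s2)
    if (keep_outcomes) {
      attr(out, "arm1") <- arm1
      attr(out, "arm2") <- arm2
    }
    out
  })
}

#' Simulate single-arm binomial pilot trials
#'
#' Draws success counts `y ~ Binomial(n, theta)` for `n_reps` independent
#' pilot trials of one homogeneous group, the setting in which an event rate
#' (consent, recruitment, attrition, outcome event) is estimated from a
#' single arm.
#'
#' @param n Pilot arm size.
#' @param theta True event rate, strictly inside (0, 1).
#' @param n_reps Number of simulated pilots.
#' @param seed Optional integer seed.
#' @return A data frame with columns `replicate`, `n`, `y`, `theta_true`.
#' @examples
#' simulate_binomial_pilot(20, 0.3, n_reps = 5, seed = 1)
#' @export
simulate_binomial_pilot <- function(n, theta, n_reps, seed = NULL) {
  n <- check_count(n, "n")
  check_number(theta, "theta", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n_reps <- check_count(n_reps, "n_reps")
  y <- with_seed(seed, stats::rbinom(n_reps, size = n, prob = theta))
  data.frame(replicate = seq_len(n_reps), n = n, y = y, theta_true = theta)
}

#' Replicates needed to estimate an event rate to a standard-error target
#'
#' The Monte-Carlo standard error of a mean of `N` simulated proportions is
#' `sqrt(theta * (1 - theta) / N)`; this returns the smallest `N` bringing it
#' down to `se_target`, i.e. `ceiling(theta * (1 - theta) / se_target^2)`.
#' At the worst case `theta = 0.5` with the default target of 0.001 this is
#' 250,000 replicates.
#'
#' @param theta True event rate in (0, 1).
#' @param se_target Required standard error of the estimated mean rate.
#' @param min_reps Optional floor on the returned count.
#' @return An integer replicate count.
#' @examples
#' required_reps_binary(0.5, 0.001)  # 250000
#' required_reps_binary(0.1, 0.001)  # 90000
#' @export
required_reps_binary <- function(theta, se_target, min_reps = 1L) {
  check_number(theta, "theta", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE, allow_vector = TRUE)
  check_number(se_target, "se_target", lower = 0, strict_lower = TRUE)
  min_reps <- check_count(min_reps, "min_reps")
  x <- theta * (1 - theta) / se_target^2
  # relative slack so an exactly-attainable target is not pushed up by
  # floating-point noise (0.1 * 0.9 / 0.001^2 must give 90000, not 90001)
  as.integer(pmax(min_reps, ceiling(x * (1 - 1e-10))))
}
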