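#' Per-group sample size for a two-arm superiority trial
#'
#' Normal-approximation formula for comparing two means with common SD:
#' `n = ceiling(2 * (z_{1-alpha/2} + z_power)^2 * sd^2 / delta^2)` per group,
#' never below 2. With `delta = 0.2`, `sd = 1`, 5% two-sided alpha and 90%
#' power this gives 526 per group (1,052 in total).
#'
#' @param effect_size Target mean difference `delta` (same units as `sd`).
#' @param sd Assumed common SD (vectorised, e.g. over pilot estimates).
#' @param alpha Two-sided significance level.
#' @param power Required power.
#' @return Integer per-group sample size(s).
#' @examples
#' required_sample_size(0.2, sd = 1)  # 526 per group
#' @export
required_sample_size <- function(effect_size, sd, alpha = 0.05,
                                 power = 0.90) {
  check_number(effect_size, "effect_size", lower = 0, strict_lower = TRUE)
  check_number(sd, "sd", lower = 0, strict_lower = TRUE, allow_vector = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(power, "power", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(pmax(2L, ceiling(2 * z^2 * sd^2 / effect_size^2)))
}

#' Power of a planned two-arm trial under a known true SD
#'
#' The normal-approximation power matching [required_sample_size()]:
#' `Phi(delta * sqrt(n/2) / sd - z_{1-alpha/2})`. The second rejection
#' region's contribution `Phi(-delta*sqrt(n/2)/sd - z)` is below 1e-4 at the
#' powers studied here and is omitted for consistency with the sample-size
#' inversion.
#'
#' @param n_per_group Subjects per arm (vectorised).
#' @param effect_size Target mean difference.
#' @param true_sd Known true SD under which power is evaluated.
#' @param alpha Two-sided significance level.
#' @return Power value(s) in (0, 1).
#' @examples
#' true_power(526, 0.2)  # just above 0.90 because of the ceiling
#' @export
true_power <- function(n_per_group, effect_size, true_sd = 1, alpha = 0.05) {
  check_count(n_per_group, "n_per_group", lower = 2L, allow_vector = TRUE)
  check_number(effect_size, "effect_size", lower = 0, strict_lower = TRUE)
  check_number(true_sd, "true_sd", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  stats::pnorm(effect_size * sqrt(n_per_group / 2) / true_sd -
                 stats::qnorm(1 - alpha / 2))
}

#' Plan a definitive trial from each simulated pilot estimate
#'
#' For every pooled-SD estimate, computes the definitive-trial per-group size
#' from the (optionally inflated) estimate and the true power that size would
#' deliver if the true SD were known. Degenerate estimates (`sd_p == 0`,
#' impossible under the continuous model) are dropped with a warning and
#' counted in the `"n_degenerate"` attribute.
#'
#' @param estimates Data frame from [pilot_sd_estimates()] (columns `sd_p`,
#'   `df`).
#' @param effect_size Target standardised difference.
#' @param alpha Two-sided significance level.
#' @param target_power Power the trial is planned for.
#' @param inflate If `TRUE`, plan with `sd_p * inflation_factor(df,
#'   inflation_confidence)` instead of the crude estimate.
#' @param inflation_confidence Confidence level of the inflation factor.
#' @param true_sd True SD used to evaluate each plan's actual power.
#' @return Data frame with one row per (non-degenerate) estimate and columns
#'   `effect_size`, `alpha`, `target_power`, `sd_used`, `n_per_group`,
#'   `n_total`, `true_power`, `inflated`.
#' @examples
#' est <- pilot_sd_estimates(simulate_normal_pilot(10, 100, seed = 1))
#' plans <- plan_from_pilot(est, effect_size = 0.2)
#' mean(plans$true_power >= 0.8)
#' @export
plan_from_pilot <- function(estimates, effect_size, alpha = 0.05,
                            target_power = 0.90, inflate = FALSE,
                            inflation_confidence = 0.80, true_sd = 1) {
  if (!is.data.frame(estimates) ||
      !all(c("sd_p", "df") %in% names(estimates)) ||
      nrow(estimates) == 0) {
    stop_invalid("invalid input: `estimates` must be a nonempty data frame ",
                 "with columns sd_p and df")
  }
  degenerate <- estimates$sd_p <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate estimate(s) with sd_p = 0 excluded",
            call. = FALSE)
    estimates <- estimates[!degenerate, , drop = FALSE]
    if (nrow(estimates) == 0) {
      stop_invalid("invalid input: all estimates degenerate")
    }
  }
  sd_used <- if (inflate) {
    estimates$sd_p * inflation_factor(estimates$df, inflation_confidence)
  } else {
    estimates$sd_p
  }
  n <- required_sample_size(effect_size, sd_used, alpha, target_power)
  out <- data.frame(effect_size = effect_size,
                    alpha = alpha,
                    target_power = target_power,
                    sd_used = sd_used,
                    n_per_group = n,
                    n_total = 2L * n,
                    true_power = true_power(n, effect_size, true_sd, alpha),
                    inflated = inflate)
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Assurance: probability that a pilot-based plan reaches a power floor
#'
#' The probability, over the sampling distribution of the pooled SD from a
#' pilot with `pilot_n_per_group` per arm, that the definitive trial planned
#' for `target_power` attains at least `power_floor` true power when the true
#' SD is `true_sd`.
#'
#' Two routes are available and must agree: `"exact"` uses the chi-square
#' distribution of `df * SD_p^2 / sigma^2` — the plan reaches the floor
#' exactly when the planned `n` is at least the floor's own sample size, a
#' threshold event on `SD_p^2` — and `"simulate"` takes the empirical
#' fraction over simulated pilots.
#'
#' @param pilot_n_per_group Pilot subjects per arm.
#' @param effect_size Target standardised difference.
#' @param alpha Two-sided significance level.
#' @param target_power Power the definitive trial is planned for.
#' @param power_floor Power level that counts as success.
#' @param inflate,inflation_confidence Plan from the inflated estimate.
#' @param true_sd True SD.
#' @param method `"exact"` (closed form) or `"simulate"` (Monte Carlo).
#' @param n_reps,seed Replicates and seed for the Monte-Carlo route.
#' @return The assurance probability.
#' @examples
#' assurance(10, effect_size = 0.2)  # about 0.765
#' @export
assurance <- function(pilot_n_per_group, effect_size, alpha = 0.05,
                      target_power = 0.90, power_floor = 0.80,
                      inflate = FALSE, inflation_confidence = 0.80,
                      true_sd = 1, method = c("exact", "simulate"),
                      n_reps = 100000L, seed = NULL) {
  pilot_n_per_group <- check_count(pilot_n_per_group, "pilot_n_per_group",
                                   lower = 2L)
  check_number(power_floor, "power_floor", lower = 0, upper = 1,
               strict_upper = TRUE)
  method <- match.arg(method)
  if (power_floor <= 0) {
    return(1)
  }
  df <- 2L * (pilot_n_per_group - 1L)
  if (method == "exact") {
    # planned n/group = max(2, ceiling(K * sd_used^2)), K = 2 z^2 / delta^2;
    # the floor is met iff n >= n_floor, i.e. K * sd_used^2 > n_floor - 1
    z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(target_power)
    k <- 2 * z^2 / effect_size^2
    n_floor <- required_sample_size(effect_size, true_sd, alpha, power_floor)
    if (n_floor <= 2L) {
      return(1)
    }
    infl <- if (inflate) inflation_factor(df, inflation_confidence) else 1
    threshold_var <- (n_floor - 1) / (k * infl^2)  # on the sd_used^2 scale
    stats::pchisq(df * threshold_var / true_sd^2, df, lower.tail = FALSE)
  } else {
    est <- pilot_sd_estimates(
      simulate_normal_pilot(pilot_n_per_group, n_reps, true_sd = true_sd,
                            seed = seed))
    plans <- plan_from_pilot(est, effect_size, alpha, target_power,
                             inflate, inflation_confidence, true_sd)
    mean(plans$true_power >= power_floor)
  }
}

#' Summarise a set of definitive-trial plans
#'
#' Reduces the plans derived from one pilot size to the distribution
#' summaries behind box-and-whisker displays: percentiles (min, 2.5, 25, 50,
#' 75, 97.5, max; linear interpolation between order statistics) of true
#' power, planned total size, and grand total including the pilot itself,
#' plus the empirical assurance at the power floor.
#'
#' @param plans Data frame from [plan_from_pilot()].
#' @param pilot_total Total pilot subjects (both arms) to add to the planned
#'   size for the grand total.
#' @param power_floor Power level for the assurance fraction.
#' @return An object of class `plan_summary`: a list with elements
#'   `pilot_total`, `n_plans`, `assurance_at_floor`, `power_floor`, and
#'   percentile vectors `true_power`, `n_total`, `n_grand`.
#' @export
summarize_plans <- function(plans, pilot_total, power_floor = 0.80) {
  if (!is.data.frame(plans) || nrow(plans) == 0) {
    stop_invalid("invalid input: `plans` must be a nonempty data frame")
  }
  pilot_total <- check_count(pilot_total, "pilot_total", lower = 0L)
  probs <- c(0, 0.025, 0.25, 0.5, 0.75, 0.975, 1)
  pct <- function(x) {
    q <- stats::quantile(x, probs = probs, names = FALSE, type = 7)
    names(q) <- c("min", "p2.5", "p25", "p50", "p75", "p97.5", "max")
    q
  }
  structure(list(pilot_total = pilot_total,
                 n_plans = nrow(plans),
                 power_floor = power_floor,
                 assurance_at_floor = mean(plans$true_power >= power_floor),
                 true_power = pct(plans$true_power),
                 n_total = pct(plans$n_total),
                 n_grand = pct(plans$n_total + pilot_total)),
            class = "plan_summary")
}

#' @export
print.plan_summary <- function(x, ...) {
  cat(sprintf("Plans from a pilot of %d subjects (%d plans)\n",
              x$pilot_total, x$n_plans))
  cat(sprintf("  P(true power >= %.2f) = %.3f\n",
              x$power_floor, x$assurance_at_floor))
  tab <- rbind(`true power` = x$true_power,
               `planned total n` = x$n_total,
               `grand total (incl. pilot)` = x$n_grand)
  print(round(tab, 3))
  invisible(x)
}

#' @export
as.data.frame.plan_summary <- function(x, ...) {
  row <- c(list(pilot_total = x$pilot_total, n_plans = x$n_plans,
                power_floor = x$power_floor,
                assurance_at_floor = x$assurance_at_floor),
           as.list(stats::setNames(x$true_power,
                                   paste0("power_", names(x$true_power)))),
           as.list(stats::setNames(x$n_total,
                                   paste0("ntotal_", names(x$n_total)))),
           as.list(stats::setNames(x$n_grand,
                                   paste0("grand_", names(x$n_grand)))))
  as.data.frame(row)
}
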