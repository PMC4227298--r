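#' Precision table for the continuous outcome over the pilot-size grid
#'
#' For each per-group pilot size: simulates the pilots, and reports the mean
#' pooled SD and its bias, the Monte-Carlo and closed-form mean widths of the
#' SD confidence interval, the relative precision gain against the next grid
#' size (from both width routes), and the inflation factor at the configured
#' confidence. These are the numbers behind the SD-distribution and
#' precision-gain displays.
#'
#' @param group_sizes Per-group pilot sizes, in increasing order.
#' @param n_reps Simulated pilots per size.
#' @param true_mean,true_sd True outcome parameters.
#' @param level Confidence level of the SD interval.
#' @param inflation_confidence Confidence level of the inflation factor.
#' @param seed Master seed; each size gets a [cell_seed()] sub-stream.
#' @return Data frame with one row per size: `n_per_group`, `n_total`, `df`,
#'   `n_reps`, `mean_sd_p`, `expected_sd_p`, `bias`, `mean_ci_width`,
#'   `expected_ci_width`, `gain_next`, `gain_next_expected`,
#'   `inflation_factor`.
#' @export
continuous_precision_table <- function(group_sizes = seq(10L, 80L, by = 5L),
                                       n_reps = 10000L,
                                       true_mean = 0, true_sd = 1,
                                       level = 0.95,
                                       inflation_confidence = 0.80,
                                       seed = NULL) {
  group_sizes <- check_count(group_sizes, "group_sizes", lower = 2L,
                             allow_vector = TRUE)
  rows <- lapply(group_sizes, function(n) {
    s <- if (is.null(seed)) NULL else cell_seed(seed, "normal", n)
    est <- pilot_sd_estimates(
      simulate_normal_pilot(n, n_reps, true_mean, true_sd, seed = s))
    ci <- sd_confidence_limits(est$sd_p, est$df, level)
    df <- 2L * (n - 1L)
    data.frame(n_per_group = n, n_total = 2L * n, df = df, n_reps = n_reps,
               mean_sd_p = mean(est$sd_p),
               expected_sd_p = expected_pooled_sd(df, true_sd),
               bias = sd_bias(est$sd_p, true_sd),
               mean_ci_width = mean(ci$width),
               expected_ci_width = expected_sd_ci_width(df, level, true_sd),
               inflation_factor = inflation_factor(df, inflation_confidence))
  })
  tab <- do.call(rbind, rows)
  m <- nrow(tab)
  tab$gain_next <- c(precision_gain(tab$mean_ci_width[-m],
                                    tab$mean_ci_width[-1]), NA_real_)
  tab$gain_next_expected <- c(precision_gain(tab$expected_ci_width[-m],
                                             tab$expected_ci_width[-1]),
                              NA_real_)
  tab
}

#' Run the full pilot-sizing simulation study
#'
#' Executes the three pipelines over every grid cell of a [study_config()]:
#' the continuous-outcome precision study, the definitive-trial planning
#' study (per effect size, with and without SD inflation), and the binary
#' event-rate precision study. The same simulated pilots are reused across
#' effect sizes and inflation flags for each pilot size, so planning
#' contrasts are paired.
#'
#' @param config A `pilot_config` from [study_config()].
#' @param outdir Optional directory; when given, all tables plus a run
#'   manifest are written there via [write_study_results()].
#' @param verbose Print per-stage progress.
#' @return An object of class `pilot_study_result`: a list with elements
#'   `config`, `continuous`, `planning` (one row per effect size x inflation
#'   flag x pilot size), `binary`, and `provenance`.
#' @examples
#' cfg <- study_config(normal_group_sizes = c(10, 15), normal_reps = 500,
#'                     binary_sizes = c(10, 15), binary_thetas = c(0.2, 0.5),
#'                     binary_method = "enumerate", seed = 1)
#' res <- run_study(cfg, verbose = FALSE)
#' head(res$planning)
#' @export
run_study <- function(config = study_config(), outdir = NULL,
                      verbose = TRUE) {
  if (!inherits(config, "pilot_config")) {
    stop_invalid("config error: `config` must be a `pilot_config` object; ",
                 "see study_config()")
  }
  say <- function(...) if (verbose) message(...)

  say("continuous outcome: ", length(config$normal_group_sizes),
      " pilot sizes x ", config$normal_reps, " replicates")
  continuous <- continuous_precision_table(
    group_sizes = config$normal_group_sizes,
    n_reps = config$normal_reps,
    true_mean = config$true_mean, true_sd = config$true_sd,
    level = config$level,
    inflation_confidence = config$inflation_confidence,
    seed = config$seed)

  say("planning: ", length(config$effect_sizes),
      " effect sizes x 2 inflation settings")
  planning <- list()
  for (n in config$normal_group_sizes) {
    est <- pilot_sd_estimates(
      simulate_normal_pilot(n, config$normal_reps, config$true_mean,
                            config$true_sd,
                            seed = cell_seed(config$seed, "plan", n)))
    for (delta in config$effect_sizes) {
      for (inflate in c(FALSE, TRUE)) {
        plans <- plan_from_pilot(est, delta, config$alpha,
                                 config$target_power, inflate,
                                 config$inflation_confidence,
                                 config$true_sd)
        s <- as.data.frame(summarize_plans(plans, 2L * n,
                                           config$power_floor))
        planning[[length(planning) + 1L]] <-
          cbind(data.frame(effect_size = delta, inflated = inflate,
                           n_per_group = n), s)
      }
    }
  }
  planning <- do.call(rbind, planning)

  say("binary outcome: ", length(config$binary_thetas), " rates x ",
      length(config$binary_sizes), " sizes (", config$binary_method, ")")
  binary <- binary_precision_table(
    thetas = config$binary_thetas, sizes = config$binary_sizes,
    method = config$binary_method, se_target = config$binary_se_target,
    min_reps = config$binary_min_reps, level = config$level,
    seed = config$seed)

  result <- structure(
    list(config = config,
         continuous = continuous,
         planning = planning,
         binary = binary,
         provenance = list(
           package = "pilotsize",
           version = as.character(utils::packageVersion("pilotsize")),
           seed = config$seed,
           timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))),
    class = "pilot_study_result")
  if (!is.null(outdir)) {
    write_study_results(result, outdir)
  }
  result
}

#' @export
print.pilot_study_result <- function(x, ...) {
  cat("Pilot-sizing simulation study (seed ", x$config$seed, ")\n", sep = "")
  cat("  continuous table: ", nrow(x$continuous), " pilot sizes\n", sep = "")
  cat("  planning table:   ", nrow(x$planning), " rows\n", sep = "")
  cat("  binary table:     ", nrow(x$binary), " cells\n", sep = "")
  invisible(x)
}

#' Write all study tables and a run manifest to a directory
#'
#' One CSV per table (`continuous.csv`, `planning.csv`, `binary.csv`; UTF-8,
#' comma-separated, header row, full double precision) plus `manifest.json`
#' echoing the resolved configuration and provenance, so a run can be
#' reproduced from its own output directory.
#'
#' @param result A `pilot_study_result` from [run_study()].
#' @param outdir Output directory; created if missing.
#' @return Invisibly, the paths written.
#' @export
write_study_results <- function(result, outdir) {
  if (!inherits(result, "pilot_study_result")) {
    stop_invalid("invalid input: `result` must come from run_study()")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(continuous = file.path(outdir, "continuous.csv"),
             planning = file.path(outdir, "planning.csv"),
             binary = file.path(outdir, "binary.csv"),
             manifest = file.path(outdir, "manifest.json"))
  utils::write.csv(result$continuous, paths["continuous"], row.names = FALSE)
  utils::write.csv(result$planning, paths["planning"], row.names = FALSE)
  utils::write.csv(result$binary, paths["binary"], row.names = FALSE)
  jsonlite::write_json(list(config = unclass(result$config),
                            provenance = result$provenance),
                       paths["manifest"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
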