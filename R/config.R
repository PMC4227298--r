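#' Study configuration for a pilot-sizing simulation study
#'
#' Bundles every tunable of the simulation study into one validated object:
#' the grid of pilot sizes for the continuous (two-arm normal) and binary
#' (single-arm binomial) outcomes, the true parameter values, replicate-count
#' rules, and the planning settings (standardised effect sizes, significance
#' level, target power, power floor, inflation confidence).
#'
#' The defaults are the study conditions the package is built around: balanced
#' two-arm normal pilots of 10 to 80 subjects per group in steps of five with
#' 10,000 replicates per size, true mean 0 and true SD 1; single-arm binomial
#' pilots of 10 to 200 subjects in steps of five with true event rates 0.10 to
#' 0.50 in steps of 0.05, replicated until the event rate is estimated to
#' within a standard error of 0.001 (at least 10,000 replicates); standardised
#' effect sizes 0.2, 0.35 and 0.5; two-sided alpha 0.05; 90% target power; an
#' 80% power floor for assurance; and an 80% confidence level for the
#' variance-inflation adjustment.
#'
#' @param normal_group_sizes Integer vector of per-group pilot sizes for the
#'   continuous outcome (each at least 2, so the pooled variance has at least
#'   one degree of freedom per arm).
#' @param normal_reps Number of simulated pilots per continuous grid size.
#' @param true_mean,true_sd True mean and SD of the normal outcome.
#' @param binary_sizes Integer vector of single-arm pilot sizes for the binary
#'   outcome.
#' @param binary_thetas True event rates, each strictly inside (0, 1).
#' @param binary_se_target Standard-error target that sets the binary
#'   replicate count via [required_reps_binary()].
#' @param binary_min_reps Floor on the binary replicate count.
#' @param binary_method `"simulate"` draws binomial replicates (the
#'   Monte-Carlo procedure); `"enumerate"` computes the same cell summaries
#'   exactly by probability-weighted enumeration over all outcomes.
#' @param effect_sizes Standardised effect sizes (mean difference over SD) for
#'   the definitive-trial planning step.
#' @param alpha Two-sided significance level of the definitive trial.
#' @param target_power Power the definitive trial is planned for.
#' @param power_floor Power floor used for assurance summaries; must be below
#'   `target_power`.
#' @param inflation_confidence One-sided confidence level of the SD inflation
#'   factor, in [0.5, 1).
#' @param level Confidence level for all interval estimates.
#' @param seed Master seed; every grid cell derives its own sub-stream from it
#'   via [cell_seed()].
#' @return An object of class `pilot_config` (a validated named list).
#' @seealso [read_study_config()], [run_study()]
#' @examples
#' cfg <- study_config(seed = 1)
#' cfg$effect_sizes
#' @export
study_config <- function(normal_group_sizes = seq(10L, 80L, by = 5L),
                         normal_reps = 10000L,
                         true_mean = 0,
                         true_sd = 1,
                         binary_sizes = seq(10L, 200L, by = 5L),
                         binary_thetas = seq(0.10, 0.50, by = 0.05),
                         binary_se_target = 0.001,
                         binary_min_reps = 10000L,
                         binary_method = c("simulate", "enumerate"),
                         effect_sizes = c(0.2, 0.35, 0.5),
                         alpha = 0.05,
                         target_power = 0.90,
                         power_floor = 0.80,
                         inflation_confidence = 0.80,
                         level = 0.95,
                         seed = 20140703L) {
  cfg <- list(
    normal_group_sizes = check_count(normal_group_sizes, "normal_group_sizes",
                                     lower = 2L, allow_vector = TRUE),
    normal_reps = check_count(normal_reps, "normal_reps"),
    true_mean = check_number(true_mean, "true_mean"),
    true_sd = check_number(true_sd, "true_sd", lower = 0, strict_lower = TRUE),
    binary_sizes = check_count(binary_sizes, "binary_sizes",
                               lower = 1L, allow_vector = TRUE),
    binary_thetas = check_number(binary_thetas, "binary_thetas",
                                 lower = 0, upper = 1, strict_lower = TRUE,
                                 strict_upper = TRUE, allow_vector = TRUE),
    binary_se_target = check_number(binary_se_target, "binary_se_target",
                                    lower = 0, strict_lower = TRUE),
    binary_min_reps = check_count(binary_min_reps, "binary_min_reps"),
    binary_method = match.arg(binary_method),
    effect_sizes = check_number(effect_sizes, "effect_sizes",
                                lower = 0, strict_lower = TRUE,
                                allow_vector = TRUE),
    alpha = check_number(alpha, "alpha", lower = 0, upper = 1,
                         strict_lower = TRUE, strict_upper = TRUE),
    target_power = check_number(target_power, "target_power", lower = 0,
                                upper = 1, strict_lower = TRUE,
                                strict_upper = TRUE),
    power_floor = check_number(power_floor, "power_floor", lower = 0,
                               upper = 1, strict_upper = TRUE),
    inflation_confidence = check_number(inflation_confidence,
                                        "inflation_confidence",
                                        lower = 0.5, upper = 1,
                                        strict_upper = TRUE),
    level = check_number(level, "level", lower = 0, upper = 1,
                         strict_lower = TRUE, strict_upper = TRUE),
    seed = check_count(seed, "seed", lower = 0L)
  )
  if (cfg$power_floor >= cfg$target_power) {
    stop_invalid("invalid config: `power_floor` must be below `target_power`")
  }
  structure(cfg, class = "pilot_config")
}

#' Read a study configuration from a YAML or JSON file
#'
#' Fields absent from the file keep their [study_config()] defaults; unknown
#' fields are an error (they are almost always typos).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param seed Optional seed overriding the file's (and the default) seed,
#'   e.g. from a `--seed` command-line flag.
#' @return A `pilot_config` object.
#' @export
read_study_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    stop_invalid("config error: file not found: ", path)
  }
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(fields)) fields <- list()
  known <- names(formals(study_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0) {
    stop_invalid("config error: unknown field(s): ",
                 paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) fields$seed <- seed
  do.call(study_config, fields)
}

#' @export
print.pilot_config <- function(x, ...) {
  cat("Pilot-study simulation configuration\n")
  cat("  continuous: per-group sizes", min(x$normal_group_sizes), "to",
      max(x$normal_group_sizes), sprintf("(%d sizes), %d replicates each\n",
                                         length(x$normal_group_sizes),
                                         x$normal_reps))
  cat("  true outcome: mean", x$true_mean, ", SD", x$true_sd, "\n")
  cat("  binary: sizes", min(x$binary_sizes), "to", max(x$binary_sizes),
      sprintf("(%d sizes) x %d event rates, method '%s'\n",
              length(x$binary_sizes), length(x$binary_thetas),
              x$binary_method))
  cat("  planning: effect sizes", paste(x$effect_sizes, collapse = ", "),
      sprintf("| alpha %.3g, power %.2f, floor %.2f, inflation conf %.2f\n",
              x$alpha, x$target_power, x$power_floor,
              x$inflation_confidence))
  cat("  interval level", x$level, "| seed", x$seed, "\n")
  invisible(x)
}
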