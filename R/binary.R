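#' Wilson score interval for a binomial proportion
#'
#' Inverts the score test: with `phat = y/n` and `z` the standard-normal
#' quantile at `1 - (1 - level)/2`, the interval has centre
#' `(phat + z^2/2n) / (1 + z^2/n)` and half-width
#' `z * sqrt(phat(1 - phat)/n + z^2/4n^2) / (1 + z^2/n)`. Unlike the Wald
#' interval it never extends outside [0, 1]; endpoints are clamped only to
#' absorb floating-point noise at `y = 0` and `y = n`.
#'
#' @param y Success count(s), each in `0..n`.
#' @param n Trials (vectorised with `y`).
#' @param level Confidence level.
#' @return Data frame with columns `y`, `n`, `theta_hat`, `lower`, `upper`,
#'   `width`, `level`.
#' @examples
#' wilson_interval(30, 60)
#' wilson_interval(0, 10)$lower  # exactly 0
#' @export
wilson_interval <- function(y, n, level = 0.95) {
  check_count(n, "n", allow_vector = TRUE)
  check_number(y, "y", allow_vector = TRUE)
  if (any(y != trunc(y)) || any(y < 0) || any(y > n)) {
    stop_invalid("invalid input: `y` must be a whole number in [0, n]")
  }
  check_number(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- y / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  lower <- pmax(0, centre - half)
  upper <- pmin(1, centre + half)
  # the score bounds are exactly 0 at y = 0 and 1 at y = n; snap away the
  # floating-point residue so boundary cells are exact
  lower[phat == 0] <- 0
  upper[phat == 1] <- 1
  data.frame(y = y, n = n, theta_hat = phat,
             lower = lower, upper = upper,
             width = upper - lower, level = level)
}

#' Exact expectation of a Wilson-interval summary over binomial outcomes
#'
#' Computes `sum_{y=0}^{n} P(Y = y) * q(y)` with `Y ~ Binomial(n, theta)` and
#' `q(y)` the interval width, the coverage indicator (closed interval:
#' endpoint equality counts as covering), or the point estimate `y/n`. This
#' deterministic enumeration is the infinite-replicate limit of the
#' Monte-Carlo cell summaries and serves as their oracle.
#'
#' @param theta True event rate in (0, 1).
#' @param n Arm size.
#' @param quantity One of `"width"`, `"coverage"`, `"theta_hat"`.
#' @param level Confidence level of the interval.
#' @return The exact expectation.
#' @examples
#' enumerate_binomial_expectation(0.3, 20, "coverage")
#' @export
enumerate_binomial_expectation <- function(theta, n,
                                           quantity = c("width", "coverage",
                                                        "theta_hat"),
                                           level = 0.95) {
  check_number(theta, "theta", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n <- check_count(n, "n")
  quantity <- match.arg(quantity)
  y <- 0:n
  w <- stats::dbinom(y, n, theta)
  iv <- wilson_interval(y, n, level)
  q <- switch(quantity,
              width = iv$width,
              coverage = as.numeric(iv$lower <= theta & theta <= iv$upper),
              theta_hat = iv$theta_hat)
  sum(w * q)
}

#' Summarise one (event rate, pilot size) cell of the binary study
#'
#' For a single-arm pilot of size `n` with true event rate `theta`, returns
#' the mean observed rate, its signed bias, the mean Wilson-interval width,
#' and the coverage probability of the interval. `method = "simulate"`
#' mirrors the Monte-Carlo study procedure (replicates set by the
#' standard-error rule unless `n_reps` is given); `method = "enumerate"`
#' computes the same quantities exactly by probability-weighted enumeration.
#'
#' @param theta True event rate in (0, 1).
#' @param n Pilot arm size.
#' @param method `"enumerate"` (exact) or `"simulate"` (Monte Carlo).
#' @param n_reps Replicates for the Monte-Carlo route; default
#'   `required_reps_binary(theta, se_target, min_reps)`.
#' @param se_target,min_reps Replicate-count rule for the default `n_reps`.
#' @param level Confidence level.
#' @param seed Optional seed for the Monte-Carlo route.
#' @return One-row data frame with columns `theta_true`, `n`, `n_reps`
#'   (`NA` for enumeration), `method`, `mean_theta_hat`, `bias`,
#'   `mean_width`, `coverage`.
#' @examples
#' summarize_binomial_cell(0.5, 60, method = "enumerate")
#' @export
summarize_binomial_cell <- function(theta, n,
                                    method = c("enumerate", "simulate"),
                                    n_reps = NULL, se_target = 0.001,
                                    min_reps = 10000L, level = 0.95,
                                    seed = NULL) {
  method <- match.arg(method)
  check_number(theta, "theta", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n <- check_count(n, "n")
  if (method == "enumerate") {
    mean_th <- enumerate_binomial_expectation(theta, n, "theta_hat", level)
    width <- enumerate_binomial_expectation(theta, n, "width", level)
    cover <- enumerate_binomial_expectation(theta, n, "coverage", level)
    n_reps_used <- NA_integer_
  } else {
    if (is.null(n_reps)) {
      n_reps <- required_reps_binary(theta, se_target, min_reps)
    }
    reps <- simulate_binomial_pilot(n, theta, n_reps, seed)
    # all summaries depend on y only; tabulate once and weight by count
    counts <- tabulate(reps$y + 1L, nbins = n + 1L)
    iv <- wilson_interval(0:n, n, level)
    mean_th <- sum(counts * iv$theta_hat) / n_reps
    width <- sum(counts * iv$width) / n_reps
    cover <- sum(counts * (iv$lower <= theta & theta <= iv$upper)) / n_reps
    n_reps_used <- n_reps
  }
  data.frame(theta_true = theta, n = n, n_reps = n_reps_used,
             method = method, mean_theta_hat = mean_th,
             bias = mean_th - theta, mean_width = width, coverage = cover)
}

#' Precision table for the binary outcome over a (theta, n) grid
#'
#' One row per cell: the [summarize_binomial_cell()] summaries plus the
#' relative precision gain against the next grid size up within the same
#' event rate (the cell at size `n` reports the width reduction obtained by
#' moving to the following size).
#'
#' @param thetas True event rates.
#' @param sizes Pilot arm sizes (the gain column compares consecutive
#'   entries, so pass them in increasing order).
#' @param method,se_target,min_reps,level As [summarize_binomial_cell()].
#' @param seed Master seed; each cell gets a [cell_seed()] sub-stream.
#' @return Data frame, one row per (theta, n) cell, with column `gain_next`
#'   (`NA` for the last size of each rate).
#' @export
binary_precision_table <- function(thetas = seq(0.10, 0.50, by = 0.05),
                                   sizes = seq(10L, 200L, by = 5L),
                                   method = c("enumerate", "simulate"),
                                   se_target = 0.001, min_reps = 10000L,
                                   level = 0.95, seed = NULL) {
  method <- match.arg(method)
  rows <- vector("list", length(thetas) * length(sizes))
  k <- 0
  for (th in thetas) {
    for (n in sizes) {
      k <- k + 1
      s <- if (is.null(seed)) NULL else cell_seed(seed, "binary", th, n)
      rows[[k]] <- summarize_binomial_cell(th, n, method = method,
                                           se_target = se_target,
                                           min_reps = min_reps,
                                           level = level, seed = s)
    }
  }
  tab <- do.call(rbind, rows)
  tab$gain_next <- NA_real_
  for (th in thetas) {
    i <- which(tab$theta_true == th)
    i <- i[order(tab$n[i])]
    if (length(i) > 1) {
      w <- tab$mean_width[i]
      tab$gain_next[i[-length(i)]] <- precision_gain(w[-length(w)], w[-1])
    }
  }
  tab
}
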