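# Internal argument checks and deterministic seeding helpers.

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_vector = FALSE) {
  if (!is.numeric(x) || anyNA(x) || (!allow_vector && length(x) != 1L)) {
    stop_invalid("invalid parameter: `", name, "` must be ",
                 if (allow_vector) "a numeric vector" else "a single number",
                 " without missing values")
  }
  lo_ok <- if (strict_lower) all(x > lower) else all(x >= lower)
  hi_ok <- if (strict_upper) all(x < upper) else all(x <= upper)
  if (!lo_ok || !hi_ok) {
    stop_invalid("invalid parameter: `", name, "` must lie in ",
                 if (strict_lower) "(" else "[", lower, ", ", upper,
                 if (strict_upper) ")" else "]")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L, allow_vector = FALSE) {
  check_number(x, name, lower = lower, allow_vector = allow_vector)
  if (any(x != trunc(x))) {
    stop_invalid("invalid parameter: `", name, "` must be a whole number")
  }
  invisible(as.integer(x))
}

#' Derive a reproducible sub-stream seed for one grid cell
#'
#' Hashes a master seed together with an arbitrary list of labels (grid cell
#' identifiers such as the outcome type, true proportion, or group size) into
#' a single integer seed. Cells can then be simulated in any order, or in
#' isolation, and still reproduce the exact replicates a full run would have
#' produced.
#'
#' @param seed Master integer seed.
#' @param ... Labels identifying the cell; coerced to character.
#' @return A single positive integer seed, below 2^31.
#' @examples
#' cell_seed(1, "normal", 35)
#' @export
cell_seed <- function(seed, ...) {
  check_count(seed, "seed", lower = 0L)
  label <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (b in utf8ToInt(label)) {
    h <- (h * 131 + b) %% 2147483587
  }
  as.integer(h + 1)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  check_count(seed, "seed", lower = 0L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
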