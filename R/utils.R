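#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`, then
#' restores the previous RNG state so callers' random streams are unaffected.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Nearest-sample index offset for a latency in ms at sampling rate fs.
ms_to_samples <- function(ms, fs) {
  as.integer(round(ms * fs / 1000))
}

samples_to_ms <- function(k, fs) {
  k * 1000 / fs
}

# Columns of a time axis falling inside [window[1], window[2]] ms (inclusive).
window_index <- function(time_ms, window_ms) {
  if (window_ms[1] < min(time_ms) - 1e-9 || window_ms[2] > max(time_ms) + 1e-9) {
    abort("`window_ms` lies outside the series time axis.", class = "gng_parameter_error")
  }
  which(time_ms >= window_ms[1] - 1e-9 & time_ms <= window_ms[2] + 1e-9)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name),
      class = "gng_parameter_error")
  }
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s number.", name,
      if (strict) "positive" else "non-negative"), class = "gng_parameter_error")
  }
  invisible(x)
}

sample_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 <= 0) return(NA_real_)
  mean(x^4) / m2^2
}
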