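#' Sample-wise paired permutation t-test on waveforms
#'
#' For each time sample, computes the paired t statistic on within-subject
#' condition differences and a permutation p value under the sign-flip null:
#' each permutation flips the sign of entire subject difference *series*
#' (whole-series flips preserve the temporal autocorrelation of the null).
#' Two-sided p per sample is `(#{|t*| >= |t_obs|} + 1) / (n_perm + 1)` for
#' random flips, or the exact proportion over all `2^n` flip patterns when
#' `exhaustive = TRUE`. Samples with `p < alpha` form the significance mask,
#' and maximal runs of at least `min_consec` consecutive significant samples
#' are reported with their time extents.
#'
#' @param cond_a,cond_b Subjects x samples matrices on a common time axis,
#'   same subject order (paired).
#' @param time_ms Time axis (length = columns of the matrices).
#' @param window_ms Optional analysis window, e.g. `c(-50, 150)`.
#' @param alpha Per-sample significance level (default 0.01).
#' @param min_consec Minimum run length in samples (default 5, about 40 ms
#'   at 128 Hz).
#' @param n_perm Number of random sign-flip permutations (default 2000).
#' @param seed Seed for the permutation draws.
#' @param exhaustive Enumerate all `2^n` sign patterns (n <= 20) instead of
#'   sampling.
#' @return A `gng_permtest` object: per-sample `t`, `p`, `significant`;
#'   `runs` (tibble of maximal significant runs with `start_ms`, `end_ms`,
#'   `n_samples`); `t_range`; and the test configuration.
#' @export
samplewise_permutation_test <- function(cond_a, cond_b, time_ms,
                                        window_ms = NULL, alpha = 0.01,
                                        min_consec = 5, n_perm = 2000,
                                        seed = NULL, exhaustive = FALSE) {
  cond_a <- as.matrix(cond_a)
  cond_b <- as.matrix(cond_b)
  if (!all(dim(cond_a) == dim(cond_b)) || ncol(cond_a) != length(time_ms)) {
    abort("Condition matrices must be subjects x samples with matching axes.",
      class = "gng_data_error")
  }
  n <- nrow(cond_a)
  if (n < 2) abort("Need at least 2 paired subjects.", class = "gng_data_error")
  D <- cond_a - cond_b
  if (!is.null(window_ms)) {
    idx <- window_index(time_ms, window_ms)
    D <- D[, idx, drop = FALSE]
    time_ms <- time_ms[idx]
  }
  ss <- colSums(D^2)

  t_of_means <- function(m) {
    # sign flips leave per-subject squares unchanged: only the mean moves
    v <- (rep(ss, each = NROW(m)) - n * m^2) / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    tt <- m / se
    tt[se == 0] <- ifelse(abs(m[se == 0]) < 1e-12, 0, sign(m[se == 0]) * Inf)
    tt
  }
  t_obs <- as.numeric(t_of_means(matrix(colMeans(D), 1)))

  flips <- if (exhaustive) {
    if (n > 20) abort("Exhaustive enumeration limited to n <= 20.",
      class = "gng_parameter_error")
    g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    colnames(g) <- NULL
    g
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
      ncol = n))
  }
  m_perm <- (flips %*% D) / n
  t_perm <- t_of_means(m_perm)
  exceed <- colSums(abs(t_perm) >= rep(abs(t_obs) - 1e-12, each = nrow(flips)))
  p <- if (exhaustive) exceed / nrow(flips) else (exceed + 1) / (nrow(flips) + 1)

  mask <- p < alpha
  runs <- significant_runs(mask, time_ms, min_consec)

  structure(
    list(time_ms = time_ms, t = t_obs, p = p, significant = mask, runs = runs,
      t_range = range(t_obs), alpha = alpha, min_consec = min_consec,
      n_perm = nrow(flips), n_subjects = n, seed = seed,
      exhaustive = exhaustive),
    class = "gng_permtest"
  )
}

significant_runs <- function(mask, time_ms, min_consec) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_consec
  tibble::tibble(
    start_ms = time_ms[starts[keep]],
    end_ms = time_ms[ends[keep]],
    n_samples = r$lengths[keep]
  )
}

#' @export
print.gng_permtest <- function(x, ...) {
  cat(sprintf("<gng_permtest> %d subjects, %d samples in [%g, %g] ms, %s%d permutations\n",
    x$n_subjects, length(x$t), min(x$time_ms), max(x$time_ms),
    if (x$exhaustive) "exhaustive " else "", x$n_perm))
  cat(sprintf("  observed t range: %.2f to %.2f; %d significant sample(s) at p < %g\n",
    x$t_range[1], x$t_range[2], sum(x$significant), x$alpha))
  if (nrow(x$runs)) {
    for (i in seq_len(nrow(x$runs))) {
      cat(sprintf("  run: [%g, %g] ms (%d samples)\n", x$runs$start_ms[i],
        x$runs$end_ms[i], x$runs$n_samples[i]))
    }
  } else {
    cat(sprintf("  no runs of >= %d consecutive significant samples\n", x$min_consec))
  }
  invisible(x)
}

#' Wilcoxon signed-rank test with normal approximation
#'
#' Paired signed-rank test: zero differences are removed, `W` is the sum of
#' positive ranks of |differences|, and `Z` uses the closed-form null mean
#' `n(n+1)/4` and tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48` (no continuity correction). Two-sided
#' p from the normal approximation. Returns an absent (all-`NA`) result when
#' every difference is zero.
#'
#' @param x,y Paired numeric vectors (`y` omitted for one-sample use on
#'   differences).
#' @return A one-row tibble: `W`, `Z`, `p`, `n` (non-zero differences),
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(tibble::tibble(W = NA_real_, Z = NA_real_, p = NA_real_, n = 0L,
      method = "wilcoxon_signed_rank"))
  }
  if (n < 5L) {
    warn("Fewer than 5 non-zero differences; normal approximation is crude.")
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  Z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  tibble::tibble(W = W, Z = Z, p = 2 * pnorm(-abs(Z)), n = n,
    method = "wilcoxon_signed_rank")
}

#' Friedman rank test across repeated conditions
#'
#' Thin wrapper over [stats::friedman.test()] for a subjects x conditions
#' matrix with complete rows.
#'
#' @param m Numeric matrix, one row per subject, `k >= 3` columns.
#' @return A one-row tibble: `chisq`, `df`, `p`, `n`, `method`.
#' @export
friedman_rank_test <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 3L) abort("Need k >= 3 conditions.", class = "gng_data_error")
  if (any(!complete.cases(m))) {
    abort("Incomplete rows in Friedman input.", class = "gng_data_error")
  }
  ft <- stats::friedman.test(m)
  chisq <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(chisq)) {
    # every row fully tied: the tie correction divides 0 by 0; the
    # uncorrected statistic is 0 (mid-ranks everywhere)
    chisq <- 0
    p <- 1
  }
  tibble::tibble(chisq = chisq, df = unname(ft$parameter),
    p = p, n = nrow(m), method = "friedman")
}

#' Signed area of a waveform over a time window
#'
#' Trapezoidal integral of the series between the window bounds (units:
#' value x ms). Samples strictly inside the window are used; the window must
#' lie within the series' time axis.
#'
#' @param series A `gng_roi` tibble, or a numeric vector with `time_ms`
#'   supplied.
#' @param window_ms Two-element window.
#' @param time_ms Time axis for vector input.
#' @return The signed area.
#' @export
waveform_area <- function(series, window_ms, time_ms = NULL) {
  if (inherits(series, "gng_roi") || is.data.frame(series)) {
    time_ms <- series$time_ms
    values <- series$value
  } else {
    values <- series
  }
  idx <- window_index(time_ms, window_ms)
  pracma::trapz(time_ms[idx], values[idx])
}

#' One-way ANOVA over pooled observations
#'
#' Classical between/within decomposition with `df1 = k - 1` and
#' `df2 = N - k`; observations are pooled as independent units (e.g. one
#' waveform area per subject and tertile). With zero within-group variance
#' the F ratio is 0 when the group means agree and an error otherwise
#' (undefined F).
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @return A one-row tibble: `F`, `df1`, `df2`, `p`, `method`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) abort("Need k >= 2 groups.", class = "gng_data_error")
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ss_within <- tab["Residuals", "Sum Sq"]
  ss_between <- tab[1, "Sum Sq"]
  if (ss_within <= .Machine$double.eps * max(1, ss_between)) {
    if (ss_between <= .Machine$double.eps) {
      return(tibble::tibble(F = 0, df1 = tab[1, "Df"], df2 = tab["Residuals", "Df"],
        p = 1, method = "oneway_anova"))
    }
    abort("Zero within-group variance with unequal means: F undefined.",
      class = "gng_data_error")
  }
  tibble::tibble(F = tab[1, "F value"], df1 = tab[1, "Df"],
    df2 = tab["Residuals", "Df"], p = tab[1, "Pr(>F)"], method = "oneway_anova")
}

#' Paired samples t-test
#'
#' Two-sided t test on paired differences (`df = n - 1`), guarding the
#' degenerate cases: identical vectors give `t = 0, p = 1`; constant nonzero
#' differences are an error.
#'
#' @param x,y Paired numeric vectors.
#' @return A one-row tibble: `t`, `df`, `p`, `n`, `method`.
#' @export
paired_t_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2L) abort("Need n >= 2 pairs.", class = "gng_data_error")
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, df = n - 1, p = 1, n = n, method = "paired_t"))
    }
    abort("Zero-variance nonzero differences: t undefined.", class = "gng_data_error")
  }
  tt <- stats::t.test(x[ok], y[ok], paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, n = n, method = "paired_t")
}

#' Effect size r from a Z or t statistic
#'
#' The Rosenthal convention `r = |statistic| / sqrt(n)`, with `n` the number
#' of paired units in the comparison. Summaries report it to 2 decimals.
#'
#' @param statistic Z or t value (vectorized).
#' @param n Number of paired units.
#' @return `r` in `[0, 1]` for statistics within the usual range.
#' @examples
#' effect_size_r(7.99, 93)
#' @export
effect_size_r <- function(statistic, n) {
  if (any(n <= 0)) abort("`n` must be positive.", class = "gng_parameter_error")
  abs(statistic) / sqrt(n)
}

#' Bonferroni-adjusted significance level
#'
#' `family_alpha / m`, rounded to 4 decimals for display (the convention
#' used when reporting post hoc thresholds, e.g. 0.05 / 3 = 0.0167).
#'
#' @param family_alpha Family-wise level (e.g. 0.05).
#' @param m Number of comparisons (>= 1).
#' @return The adjusted level.
#' @examples
#' bonferroni_alpha(0.05, 3)
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (any(m < 1)) abort("`m` must be >= 1.", class = "gng_parameter_error")
  round(family_alpha / m, 4)
}
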