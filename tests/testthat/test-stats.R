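# Independent exhaustive sign-flip oracle: explicit loops, no shared code
# with the implementation.
oracle_signflip <- function(D) {
  n <- nrow(D); S <- ncol(D)
  t_of <- function(d) {
    m <- mean(d); s <- sd(d)
    if (s == 0) return(if (abs(m) < 1e-12) 0 else sign(m) * Inf)
    m / (s / sqrt(n))
  }
  t_obs <- apply(D, 2, t_of)
  count <- integer(S)
  for (bits in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(bits, 2^(seq_len(n) - 1)) > 0, -1, 1)
    Df <- D * signs
    for (s in seq_len(S)) {
      if (abs(t_of(Df[, s])) >= abs(t_obs[s]) - 1e-12) count[s] <- count[s] + 1L
    }
  }
  list(t = t_obs, p = count / 2^n)
}

test_that("identical conditions give zero significant samples", {
  m <- matrix(rnorm(8 * 12), 8, 12)
  r <- samplewise_permutation_test(m, m, time_ms = seq_len(12), n_perm = 200,
    seed = 1)
  expect_equal(sum(r$significant), 0)
  expect_equal(r$t, rep(0, 12))
})

test_that("a large constant difference over 8 subjects reaches p = 2/256", {
  set.seed(2)
  base <- matrix(rnorm(8 * 10), 8, 10)
  a <- base + 50
  r <- samplewise_permutation_test(a, base, time_ms = seq_len(10),
    exhaustive = TRUE)
  # only the identity and the global flip tie the observed |t|
  expect_equal(r$p, rep(2 / 256, 10))
  expect_true(all(r$significant))
  expect_equal(nrow(r$runs), 1)
  expect_equal(r$runs$n_samples, 10)
})

test_that("the permutation test matches an exhaustive sign-flip oracle", {
  set.seed(3)
  D <- matrix(rnorm(8 * 6), 8, 6) + rep(c(0, 0, 1.5, 1.5, 0, 0), each = 8)
  a <- matrix(rnorm(8 * 6), 8, 6)
  b <- a - D
  r <- samplewise_permutation_test(a, b, time_ms = seq_len(6), exhaustive = TRUE)
  o <- oracle_signflip(a - b)
  expect_equal(r$t, o$t, tolerance = 1e-10)
  expect_equal(r$p, o$p, tolerance = 1e-12)
})

test_that("runs shorter than min_consec are not reported", {
  set.seed(4)
  # effect confined to 4 samples out of 12
  D <- matrix(rnorm(8 * 12, 0, 0.1), 8, 12)
  D[, 3:6] <- D[, 3:6] + 50
  a <- matrix(rnorm(8 * 12), 8, 12)
  r <- samplewise_permutation_test(a, a - D, time_ms = seq_len(12),
    exhaustive = TRUE, min_consec = 5)
  expect_gte(sum(r$significant), 4)
  expect_equal(nrow(r$runs), 0)
})

test_that("whole-series flips keep within-series structure intact", {
  set.seed(5)
  a <- matrix(rnorm(10 * 20), 10, 20)
  b <- matrix(rnorm(10 * 20), 10, 20)
  r1 <- samplewise_permutation_test(a, b, seq_len(20), n_perm = 300, seed = 9)
  r2 <- samplewise_permutation_test(a, b, seq_len(20), n_perm = 300, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_error(
    samplewise_permutation_test(a, b[1:9, ], seq_len(20)),
    class = "gng_data_error")
})

test_that("Wilcoxon signed-rank matches the closed-form normal approximation", {
  x <- c(5, 7, 3, 9, 4, 6, 8, 2, 7, 5)
  y <- x - seq(0.1, 1, by = 0.1)   # all 10 differences positive, untied
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$W, 55)
  # closed-form null: mean n(n+1)/4 = 27.5, variance n(n+1)(2n+1)/24 = 96.25
  expect_equal(w$Z, (55 - 27.5) / sqrt(96.25), tolerance = 1e-9)

  expect_true(is.na(wilcoxon_signed_rank(x, x)$Z))

  w_neg <- wilcoxon_signed_rank(y, x)
  expect_equal(w_neg$Z, -w$Z)

  # agreement with the reference implementation (tie-corrected, no
  # continuity correction)
  set.seed(6)
  a <- rnorm(20); b <- rnorm(20)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("Friedman test matches the rank formula and reference implementation", {
  m <- matrix(c(1, 2, 3,
                2, 4, 6,
                1, 5, 9), 3, 3, byrow = TRUE)  # identical ordering per row
  f <- friedman_rank_test(m)
  expect_equal(f$chisq, 6)
  expect_equal(f$df, 2)

  same <- matrix(1, 4, 3)
  expect_equal(friedman_rank_test(same)$chisq, 0)

  set.seed(7)
  mm <- matrix(rnorm(24), 8, 3)
  expect_equal(friedman_rank_test(mm)$p, stats::friedman.test(mm)$p.value)

  mm[2, 3] <- NA
  expect_error(friedman_rank_test(mm), class = "gng_data_error")
})

test_that("waveform areas integrate trapezoidally over the window", {
  t_ms <- seq(-100, 300, by = 1)
  const <- rep(1, length(t_ms))
  expect_equal(waveform_area(const, c(0, 200), time_ms = t_ms), 200)

  odd <- t_ms - 100   # odd-symmetric about the window center 100
  expect_equal(waveform_area(odd, c(0, 200), time_ms = t_ms), 0)

  # smooth signal vs fine-grid rectangle oracle
  f <- function(t) sin(2 * pi * t / 180) + 0.2 * cos(2 * pi * t / 77)
  coarse_t <- gonogoeeg:::samples_to_ms(-58:70, 128)
  area <- waveform_area(f(coarse_t), c(-50, 150), time_ms = coarse_t)
  fine_t <- seq(min(coarse_t[coarse_t >= -50]), max(coarse_t[coarse_t <= 150]),
    by = 0.01)
  oracle <- sum(f(fine_t)) * 0.01
  expect_equal(area, oracle, tolerance = abs(oracle) * 0.01 + 0.5)

  expect_error(waveform_area(const, c(-200, 100), time_ms = t_ms),
    class = "gng_parameter_error")
})

test_that("one-way ANOVA reproduces pooled degrees of freedom and the SS oracle", {
  set.seed(8)
  v <- rnorm(3 * 58)
  g <- rep(1:3, each = 58)
  a <- oneway_anova(v, g)
  expect_equal(c(a$df1, a$df2), c(2, 171))

  # closed-form sum-of-squares oracle
  v2 <- c(2, 3, 4, 6, 7, 8, 10, 12, 14)
  g2 <- rep(1:3, each = 3)
  grand <- mean(v2)
  ssb <- sum(3 * (tapply(v2, g2, mean) - grand)^2)
  ssw <- sum((v2 - ave(v2, g2))^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(oneway_anova(v2, g2)$F, f_oracle, tolerance = 1e-12)

  eq <- oneway_anova(rep(5, 9), g2)
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  expect_error(oneway_anova(c(1, 1, 1, 2, 2, 2), rep(1:2, each = 3)),
    class = "gng_data_error")
})

test_that("F never decreases when a true group difference grows (fixed noise)", {
  set.seed(9)
  noise <- rnorm(60)
  g <- rep(1:3, each = 20)
  fs <- vapply(c(0, 0.5, 1, 2), function(d) {
    oneway_anova(noise + d * (g - 2), g)$F
  }, numeric(1))
  expect_true(all(diff(fs) >= 0))
})

test_that("paired t-test handles the textbook and degenerate cases", {
  x <- c(10, 12, 14)
  y <- x - c(1, 2, 3)
  tt <- paired_t_test(x, y)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(tt$df, 2)

  same <- paired_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  neg <- paired_t_test(y, x)
  expect_equal(neg$t, -tt$t)

  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)),  # constant nonzero diff
    class = "gng_data_error")
})

test_that("effect sizes and Bonferroni thresholds follow the stated conventions", {
  expect_equal(round(effect_size_r(7.99, 93), 2), 0.83)
  expect_equal(round(effect_size_r(4.38, 58), 2), 0.58)
  expect_equal(effect_size_r(0, 50), 0)
  expect_error(effect_size_r(2, 0), class = "gng_parameter_error")

  expect_equal(bonferroni_alpha(0.05, 3), 0.0167)
  expect_equal(bonferroni_alpha(0.04, 1), 0.04)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
})

test_that("tidy and glance expose the permutation test results", {
  set.seed(10)
  a <- matrix(rnorm(10 * 15), 10, 15) + 3
  b <- matrix(rnorm(10 * 15), 10, 15)
  r <- samplewise_permutation_test(a, b, seq_len(15), n_perm = 400, seed = 2)
  td <- tidy(r)
  expect_equal(nrow(td), 15)
  expect_named(td, c("time_ms", "t", "p", "significant"))
  gl <- glance(r)
  expect_equal(gl$n_subjects, 10)
  expect_equal(gl$t_min, min(td$t))
})
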