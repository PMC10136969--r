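toy_trials <- function(stimulus, response, rt = NULL, block = 1) {
  n <- length(stimulus)
  tibble::tibble(
    subject = 1, block = block, trial = stats::ave(seq_len(n), block, FUN = seq_along),
    stimulus = stimulus, onset_ms = seq_len(n) * 1200,
    response = response,
    rt_ms = if (is.null(rt)) ifelse(response, 500, NA_real_) else rt
  )
}

test_that("outcomes follow the stimulus x response contingency table", {
  tr <- classify_outcomes(toy_trials(
    c("go", "go", "nogo", "nogo"), c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(tr$outcome,
    c("hit", "omission", "false_alarm", "correct_rejection"))
  expect_error(classify_outcomes(toy_trials("blue", TRUE)), class = "gng_data_error")
})

test_that("outcome counts partition the trial set", {
  coh <- behavior_cohort()
  counts <- table(coh$trials$outcome)
  expect_equal(sum(counts), nrow(coh$trials))
  expect_setequal(names(counts),
    c("hit", "omission", "false_alarm", "correct_rejection"))
})

test_that("rt_summaries computes medians and quartiles per outcome class", {
  tr <- toy_trials(rep("nogo", 3), rep(TRUE, 3), rt = c(400, 480, 500))
  s <- rt_summaries(tr)
  expect_equal(s$median[s$measure == "error_rt_ms"], 480)

  one <- rt_summaries(toy_trials("go", TRUE, rt = 555))
  expect_equal(one$median[one$measure == "correct_rt_ms"], 555)
  expect_equal(one$q25[one$measure == "correct_rt_ms"], 555)
  expect_equal(one$q75[one$measure == "correct_rt_ms"], 555)

  none <- rt_summaries(toy_trials("go", FALSE))
  expect_false("error_rt_ms" %in% none$measure)
})

test_that("post_slowing_pairs implements next-minus-current within blocks", {
  tr <- toy_trials(c("nogo", "go", "go"), c(TRUE, TRUE, TRUE),
    rt = c(500, 650, 600))
  pairs <- post_slowing_pairs(tr, "false_alarm")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$slowing_ms, 150)
  expect_equal(pairs$next_outcome, "hit")

  # unresponded successor: pair retained, slowing undefined
  tr2 <- toy_trials(c("nogo", "go"), c(TRUE, FALSE), rt = c(500, NA))
  p2 <- post_slowing_pairs(tr2, "false_alarm")
  expect_equal(nrow(p2), 1)
  expect_true(is.na(p2$slowing_ms))
  expect_false(p2$next_responded)

  # constant-RT sequence: all slowings zero
  tr3 <- toy_trials(rep(c("nogo", "go"), 4), rep(TRUE, 8), rt = rep(500, 8))
  expect_true(all(post_slowing_pairs(tr3, "false_alarm")$slowing_ms == 0))

  # block boundary: last trial of a block pairs with nothing
  tr4 <- toy_trials(c("nogo", "nogo"), c(TRUE, TRUE), rt = c(500, 520),
    block = c(1, 2))
  expect_equal(nrow(post_slowing_pairs(tr4, "false_alarm")), 0)
})

test_that("RT matching cannot discriminate identical pools and is deterministic", {
  pes <- tibble::tibble(rt_ms = c(400, 450, 480), slowing_ms = c(100, 150, 120),
    next_outcome = "hit", next_responded = TRUE)
  pcs <- tibble::tibble(rt_ms = rep(500, 6), slowing_ms = c(0, 10, -5, 20, 5, 0),
    next_outcome = "hit", next_responded = TRUE)
  m <- rt_matched_pcs(pes, pcs, n_repeats = 20, seed = 1)
  # all PCS current RTs identical: every repeat draws 3 of the same pool,
  # and the overall mean stays within the pool's range
  expect_true(m$mean > min(pcs$slowing_ms) && m$mean < max(pcs$slowing_ms))

  m2 <- rt_matched_pcs(pes, pcs, n_repeats = 20, seed = 1)
  expect_identical(m$repeat_values, m2$repeat_values)

  # exhaustible pool: fewer PCS than PES -> replacement with a warning
  expect_warning(
    m3 <- rt_matched_pcs(pes, pcs[1:2, ], n_repeats = 5, seed = 2),
    "replacement"
  )
  expect_true(m3$with_replacement)
})

test_that("matched selection moves the current-RT distribution toward the errors", {
  set.seed(31)
  pes <- tibble::tibble(rt_ms = rnorm(40, 450, 30), slowing_ms = rnorm(40, 150, 50),
    next_outcome = "hit", next_responded = TRUE)
  pcs <- tibble::tibble(rt_ms = rnorm(200, 590, 80), slowing_ms = rnorm(200, 0, 50),
    next_outcome = "hit", next_responded = TRUE)
  sel <- gonogoeeg:::match_one_repeat(pes$rt_ms, pcs$rt_ms, replace = FALSE)
  d_matched <- ks_distance(pcs$rt_ms[sel], pes$rt_ms)
  d_unmatched <- ks_distance(pcs$rt_ms, pes$rt_ms)
  expect_lt(d_matched, d_unmatched)
})

test_that("post-event accuracy counts only responded successors", {
  pairs <- tibble::tibble(
    next_outcome = c("hit", "hit", "false_alarm", "hit"),
    next_responded = TRUE)
  expect_equal(post_accuracy(pairs), 75)

  none <- tibble::tibble(next_outcome = "omission", next_responded = FALSE)
  expect_true(is.na(post_accuracy(none)))

  pes <- tibble::tibble(rt_ms = c(400, 450), slowing_ms = c(100, 150),
    next_outcome = c("hit", "false_alarm"), next_responded = TRUE)
  pcs <- tibble::tibble(rt_ms = rnorm(10, 500, 40), slowing_ms = rnorm(10),
    next_outcome = rep(c("hit", "false_alarm"), 5), next_responded = TRUE)
  a1 <- rt_matched_control(pes, pcs, n_repeats = 10, seed = 3, "accuracy")
  a2 <- rt_matched_control(pes, pcs, n_repeats = 10, seed = 3, "accuracy")
  expect_identical(a1$repeat_values, a2$repeat_values)
})

test_that("tertile splits cut at ceiling(n/3) ranks with stable ties", {
  ts <- tertile_split(1:9)
  expect_equal(ts$sizes, c(3, 3, 3))
  expect_equal(ts$medians, c(2, 5, 8))
  expect_equal(ts$assignment, rep(1:3, each = 3))

  ts10 <- tertile_split(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  expect_equal(ts10$sizes, c(4, 3, 3))

  # ties broken by original order; sizes never differ by more than 1
  tst <- tertile_split(rep(5, 7))
  expect_equal(tst$sizes, c(3, 2, 2))
  expect_equal(tst$assignment, c(1, 1, 1, 2, 2, 3, 3))

  expect_error(tertile_split(c(1, 2)), class = "gng_split_error")
})

test_that("RSI is soa - rt with boundary and monotonicity behavior", {
  tr <- toy_trials(c("go", "go", "go"), c(TRUE, TRUE, TRUE),
    rt = c(500, 1199.9, 700))
  r <- compute_rsi(tr, soa_ms = 1200)
  expect_equal(r$rsi_ms[1], 700)
  expect_equal(r$rsi_ms[2], 1200 - 1199.9, tolerance = 1e-9)
  expect_true(is.na(r$rsi_ms[3]))          # last trial of block
  expect_true(all(diff(r$rsi_ms[1:2]) < 0) == (diff(r$rt_ms[1:2]) > 0))
})

test_that("inclusion filter enforces the 7-trial rule per cell", {
  res <- inclusion_filter(tibble::tibble(subject = 1:3, n = c(6, 7, 30)))
  expect_equal(res$retained, 2:3)
  expect_equal(res$log$retained, c(FALSE, TRUE, TRUE))

  all_in <- inclusion_filter(tibble::tibble(subject = 1:4, n = rep(10, 4)))
  expect_equal(all_in$retained, 1:4)

  # tertile context: three per-cell counts, all must reach 7 (21 overall)
  tert <- inclusion_filter(tibble::tibble(subject = 1:2,
    t1 = c(7, 7), t2 = c(7, 6), t3 = c(7, 8)))
  expect_equal(tert$retained, 1)
})

test_that("per-subject summaries expose the descriptive measure set", {
  coh <- behavior_cohort()
  s <- subject_behavior_summary(coh$trials, seed = 3)
  expect_equal(nrow(s), 60)
  expect_true(all(s$hit_pct >= 0 & s$hit_pct <= 100, na.rm = TRUE))
  tab <- cohort_behavior_table(s)
  expect_setequal(tab$measure, c("hit_pct", "false_alarm_pct", "overall_rt_ms",
    "correct_rt_ms", "error_rt_ms", "matched_pcs_ms", "pes_ms",
    "matched_pca_pct", "pea_pct"))
  expect_true(all(tab$q25 <= tab$median & tab$median <= tab$q75))
})
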