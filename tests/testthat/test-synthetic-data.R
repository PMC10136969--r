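test_that("task sequences honor block structure and stimulus probabilities", {
  p <- synth_params(n_subjects = 1, blocks_per_subject = 1)
  s <- simulate_task_sequence(p, seed = 1)
  expect_equal(nrow(s), 90)
  expect_equal(unique(diff(s$onset_ms)), p$soa_ms)

  p_all_go <- synth_params(n_subjects = 1, blocks_per_subject = 1, p_go = 1)
  expect_true(all(simulate_task_sequence(p_all_go, 1)$stimulus == "go"))

  expect_error(synth_params(p_go = 1.3), class = "gng_parameter_error")
})

test_that("sequence generation is a pure function of (params, seed)", {
  p <- synth_params(n_subjects = 3, blocks_per_subject = 2:4)
  expect_identical(simulate_task_sequence(p, 11), simulate_task_sequence(p, 11))
  expect_false(identical(simulate_task_sequence(p, 11), simulate_task_sequence(p, 12)))
})

test_that("analytic consecutive-pair probabilities match the 70/30 design", {
  pp <- consecutive_pair_probabilities(0.7)
  expect_equal(pp$probability, c(0.09, 0.21, 0.21, 0.49))
  expect_equal(sum(pp$probability), 1)
})

test_that("behavior generation respects degenerate probabilities and censoring", {
  p <- synth_params(n_subjects = 2, blocks_per_subject = 2, p_commission = 0)
  beh <- simulate_behavior(simulate_task_sequence(p, 2), p, 3)
  expect_equal(sum(beh$outcome == "false_alarm"), 0)

  p2 <- synth_params(n_subjects = 3, blocks_per_subject = 3)
  beh2 <- simulate_behavior(simulate_task_sequence(p2, 4), p2, 5)
  rts <- beh2$rt_ms[beh2$response]
  expect_true(all(rts > 0 & rts < p2$soa_ms))
  expect_true(all(is.na(beh2$rt_ms[!beh2$response])))

  empty <- simulate_behavior(simulate_task_sequence(p2, 4)[0, ], p2, 5)
  expect_equal(nrow(empty), 0)
})

test_that("behavior generation is deterministic and errors are faster", {
  p <- synth_params(n_subjects = 5, blocks_per_subject = 3)
  sq <- simulate_task_sequence(p, 6)
  expect_identical(simulate_behavior(sq, p, 7), simulate_behavior(sq, p, 7))

  beh <- simulate_behavior(sq, p, 7)
  med_err <- median(beh$rt_ms[beh$outcome == "false_alarm"], na.rm = TRUE)
  med_cor <- median(beh$rt_ms[beh$outcome == "hit"], na.rm = TRUE)
  expect_lt(med_err, med_cor)
})

test_that("RSI mechanics hold exactly: RSI + RT = SOA for responded trials", {
  coh <- behavior_cohort()
  tr <- compute_rsi(coh$trials, soa_ms = coh$params$soa_ms)
  ok <- !is.na(tr$rsi_ms)
  expect_true(any(ok))
  expect_equal(tr$rsi_ms[ok] + tr$rt_ms[ok], rep(coh$params$soa_ms, sum(ok)))
})

test_that("zero injected slowing gives near-zero median single-trial PES", {
  p <- synth_params(n_subjects = 40, blocks_per_subject = 4, pes_shift_ms = 0,
    pea_coupling = 0)
  coh <- simulate_cohort(p, 13)
  pairs <- post_slowing_pairs(coh$trials, "false_alarm")
  sl <- pairs$slowing_ms[!is.na(pairs$slowing_ms)]
  se <- 1.2533 * sd(sl) / sqrt(length(sl))
  expect_lt(abs(median(sl)), 3 * se)
})

test_that("synthetic EEG has 14 channels at 128 Hz and is deterministic", {
  coh <- eeg_cohort()
  raw <- subject_recording(coh, 1)
  expect_s3_class(raw, "gng_raw")
  expect_equal(length(raw$channels), 14)
  expect_equal(raw$fs, 128)
  expect_true(all(c("F3", "F4", "O1", "O2", "T7", "T8", "AF3", "AF4") %in%
    raw$channels))
  raw2 <- subject_recording(coh, 1)
  expect_identical(raw$data, raw2$data)

  expect_error(
    simulate_eeg(coh$trials, coh$params, 1),   # >1 subject
    class = "gng_consistency_error"
  )
})

test_that("injected ERN scales the error-minus-correct negative area monotonically", {
  areas <- vapply(c(0, 5, 10), function(amp) {
    p <- synth_params(n_subjects = 1, blocks_per_subject = 2, blink_rate_hz = 0,
      ern_amp_uv = amp, theta_gain_db = 0)
    coh <- simulate_cohort(p, 99)
    raw <- subject_recording(coh, 1)
    cfg <- fast_config()
    ep <- preprocess_erp(raw, cfg)
    err <- roi_waveform(ep, keep = !ep$rejected & ep$info$outcome == "false_alarm")
    cor <- roi_waveform(ep, keep = !ep$rejected & ep$info$outcome == "hit")
    diff_series <- err
    diff_series$value <- err$value - cor$value
    waveform_area(diff_series, c(0, 150))
  }, numeric(1))
  # same seed across amplitude levels: more injected ERN, more negative area
  expect_true(all(diff(areas) < 0))
})

test_that("random-phase theta bursts cancel in the time-domain average", {
  # construction oracle: averaging >= 200 bursts with random phase shrinks
  # the evoked mean toward zero while the mean envelope power stays high
  set.seed(42)
  fs <- 128
  t <- seq(-0.1, 0.4, by = 1 / fs)
  env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(t)))
  n_tr <- 200
  phases <- runif(n_tr, 0, 2 * pi)
  trials <- vapply(phases, function(ph) env * cos(2 * pi * 5.5 * t + ph),
    numeric(length(t)))
  evoked <- rowMeans(trials)
  power <- rowMeans(trials^2)
  expect_lt(max(abs(evoked)), 0.1 * max(env))
  expect_gt(mean(power), 0.1)
})
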