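sine_raw <- function(freqs, amps, fs = 128, dur_s = 30, n_ch = 2) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  x <- rowSums(vapply(seq_along(freqs), function(i) {
    amps[i] * sin(2 * pi * freqs[i] * t)
  }, numeric(length(t))))
  gonogoeeg:::new_gng_raw(matrix(rep(x, n_ch), ncol = n_ch),
    c("F3", "F4")[seq_len(n_ch)], fs,
    tibble::tibble(sample = integer(0), block = integer(0), trial = integer(0),
      stimulus = character(0), outcome = character(0), rt_ms = numeric(0),
      slowing_ms = numeric(0), next_outcome = character(0),
      next_responded = logical(0)))
}

test_that("FIR bandpass passes the band and suppresses stopband and DC", {
  raw <- sine_raw(10, 1)
  out <- fir_bandpass(raw, 0.5, 30)
  mid <- 1000:2800  # avoid filter edges
  expect_equal(max(abs(out$data[mid, 1])), 1, tolerance = 0.05)

  raw40 <- sine_raw(40, 1)
  out40 <- fir_bandpass(raw40, 0.5, 30)
  atten_db <- 20 * log10(max(abs(out40$data[mid, 1])) / 1)
  expect_lt(atten_db, -20)

  dc <- sine_raw(10, 0)
  dc$data <- dc$data + 5          # constant input
  outdc <- fir_bandpass(dc, 0.5, 30)
  expect_lt(max(abs(outdc$data[mid, 1])), 0.05)

  expect_error(fir_bandpass(raw, 0.5, 70), class = "gng_parameter_error")
})

test_that("epoch segmentation uses nearest-sample inclusive windows", {
  coh <- eeg_cohort()
  raw <- subject_recording(coh, 1)
  ep <- segment_epochs(raw, c(-450, 550))
  # round(-450 * 0.128) = -58 .. round(550 * 0.128) = 70, inclusive
  expect_equal(dim(ep$data)[3], 129)
  expect_equal(ep$time_ms[1], -58 * 1000 / 128)
  expect_equal(ep$time_ms[129], 70 * 1000 / 128)
  expect_equal(nrow(ep$info) + nrow(ep$dropped), nrow(raw$events))

  # baseline subtraction zeroes the per-epoch baseline mean
  epb <- baseline_correct(ep, c(-450, -50))
  idx <- which(epb$time_ms >= -450 & epb$time_ms <= -50)
  bl <- apply(epb$data[, , idx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)

  # event too close to the recording edge is excluded and logged
  ev <- raw$events[1, ]
  ev$sample <- 1L
  ep_edge <- segment_epochs(raw, c(-450, 550), events = ev)
  expect_equal(dim(ep_edge$data)[1], 0)
  expect_equal(nrow(ep_edge$dropped), 1)
  expect_equal(ep_edge$dropped$reason, "edge")
})

test_that("amplitude rejection flags threshold crossings without dropping epochs", {
  coh <- eeg_cohort()
  ep <- segment_epochs(subject_recording(coh, 2), c(-450, 550))
  n <- dim(ep$data)[1]
  ep$data[3, 5, 10] <- 111
  ep$data[4, 5, 10] <- 109
  out <- reject_epochs(ep, 110)
  expect_true(out$rejected[3])
  expect_false(out$rejected[4])
  expect_equal(sum(out$rejected) + sum(!out$rejected), n)

  zeros <- ep
  zeros$data[] <- 0
  expect_equal(sum(reject_epochs(zeros, 110)$rejected), 0)
})

test_that("pseudo-average reference zeroes the reference mean and is shift-invariant", {
  coh <- eeg_cohort()
  raw <- subject_recording(coh, 3)
  ref <- pseudo_average_reference(raw)
  ref_idx <- match(c("O1", "O2", "T7", "T8", "AF3", "AF4"), raw$channels)
  expect_lt(max(abs(rowMeans(ref$data[, ref_idx]))), 1e-9)

  shifted <- raw
  shifted$data <- shifted$data + 42
  expect_equal(pseudo_average_reference(shifted)$data, ref$data, tolerance = 1e-12)

  # one nonzero reference channel of value 6v shifts every channel by -v
  z <- raw
  z$data[] <- 0
  z$data[, match("O1", z$channels)] <- 6
  zr <- pseudo_average_reference(z)
  expect_equal(unique(as.vector(zr$data[, match("F3", z$channels)])), -1)

  bad <- raw
  bad$channels[match("O1", bad$channels)] <- "XX"
  expect_error(pseudo_average_reference(bad), class = "gng_configuration_error")
})

test_that("ROI averaging over channels and epochs commutes", {
  coh <- eeg_cohort()
  ep <- segment_epochs(subject_recording(coh, 4), c(-450, 550))
  keep <- !ep$rejected & ep$info$outcome == "hit"
  roi <- roi_waveform(ep, keep = keep)
  # trials-then-channels order
  by_trial <- apply(ep$data[keep, match(c("F3", "F4"), ep$channels), , drop = FALSE],
    c(2, 3), mean)
  expect_equal(roi$value, colMeans(by_trial), tolerance = 1e-12)
  expect_equal(attr(roi, "n_epochs"), sum(keep))

  # F3 == F4 everywhere -> ROI equals either channel
  ep2 <- ep
  ep2$data[, match("F4", ep$channels), ] <- ep2$data[, match("F3", ep$channels), ]
  roi2 <- roi_waveform(ep2, keep = keep)
  expect_equal(roi2$value,
    apply(ep2$data[keep, match("F3", ep$channels), , drop = FALSE], 3, mean))

  # two epochs v and -v average to zero
  ep3 <- ep
  ep3$data[1, , ] <- 1
  ep3$data[2, , ] <- -1
  keep3 <- rep(FALSE, dim(ep3$data)[1]); keep3[1:2] <- TRUE
  expect_equal(roi_waveform(ep3, keep = keep3)$value, rep(0, 129))
})

test_that("ICA removes blink components flagged by the reference trace", {
  raw <- blink_recording()
  filt <- fir_bandpass(raw)
  res <- remove_artifact_components(filt, reference = raw$blink_ref)
  expect_gte(sum(res$report$removed), 1)
  expect_true(all(res$report$cor_reference[res$report$removed] >= 0.7))

  bw <- raw$blink_ref > 0.5
  af3 <- match("AF3", raw$channels)
  reduction <- 1 - var(res$raw$data[bw, af3]) / var(filt$data[bw, af3])
  expect_gte(reduction, 0.8)
})

test_that("ICA with a flat reference removes nothing and reconstructs exactly", {
  coh <- eeg_cohort()   # blink-free
  raw <- fir_bandpass(subject_recording(coh, 5))
  res <- remove_artifact_components(raw, reference = numeric(nrow(raw$data)))
  expect_equal(sum(res$report$removed), 0)
  expect_equal(res$raw$data, raw$data, tolerance = 1e-9)
})

test_that("the ERP chain recovers an injected error negativity at the ROI", {
  feats <- eeg_features()
  ok <- vapply(feats, function(f) f$n_error >= 7 && !is.null(f$erp_error),
    logical(1))
  A <- stack_feature(feats[ok], "erp_error")
  B <- stack_feature(feats[ok], "erp_correct")
  tm <- feats[ok][[1]]$erp_error$time_ms
  idx <- which(tm >= 0 & tm <= 150)
  grand_diff <- colMeans(A) - colMeans(B)
  expect_lt(min(grand_diff[idx]), -2)   # clear negativity for 10 uV injection
  expect_lt(mean(grand_diff[idx]), 0)
})
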