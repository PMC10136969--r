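# Windowed-sinc (Hamming) FIR bandpass via signal::fir1. Odd tap count ->
# type-I linear phase, so single-pass filtering with group-delay
# compensation is exactly zero-phase.
design_fir_bandpass <- function(low_hz, high_hz, fs, transition_hz = 0.5) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort(sprintf("Band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz).",
      low_hz, high_hz, nyq), class = "gng_parameter_error")
  }
  taps <- ceiling(3.3 / (transition_hz / fs))
  if (taps %% 2 == 0) taps <- taps + 1
  signal::fir1(taps - 1L, c(low_hz, high_hz) / nyq, type = "pass")
}

# Zero-phase FIR filtering of a samples x channels matrix by FFT
# convolution; the symmetric kernel's group delay is compensated exactly.
apply_fir_zero_phase <- function(x, h) {
  n <- nrow(x)
  taps <- length(h)
  delay <- (taps - 1L) %/% 2L
  nfft <- stats::nextn(n + taps - 1L, 2)
  H <- fft(c(h, numeric(nfft - taps)))
  pad <- rbind(x, matrix(0, nfft - n, ncol(x)))
  y <- Re(mvfft(mvfft(pad) * H, inverse = TRUE)) / nfft
  y[delay + seq_len(n), , drop = FALSE]
}

#' Zero-phase FIR bandpass filter for continuous recordings
#'
#' Windowed-sinc (Hamming) finite impulse response filter applied per
#' channel with exact group-delay compensation, so waveform latencies are
#' preserved. Event markers are untouched.
#'
#' @param raw A `gng_raw` recording.
#' @param low_hz,high_hz Band edges; must satisfy
#'   `0 < low < high < fs/2`.
#' @param transition_hz Transition width steering the filter order
#'   (default 0.5 Hz, about 845 taps at 128 Hz).
#' @return The filtered `gng_raw`.
#' @export
fir_bandpass <- function(raw, low_hz = 0.5, high_hz = 30, transition_hz = 0.5) {
  stopifnot(inherits(raw, "gng_raw"))
  h <- design_fir_bandpass(low_hz, high_hz, raw$fs, transition_hz)
  raw$data <- apply_fir_zero_phase(raw$data, h)
  raw
}

#' Segment a recording into response-locked epochs
#'
#' Slices a window around every event onto a common time axis. The sample
#' holding latency `t` ms is `event_sample + round(t * fs / 1000)`; with the
#' default window \[-450, 550\] ms at 128 Hz that is offsets -58..70, i.e.
#' 129 samples per epoch, endpoints inclusive. Events too close to a
#' recording edge for a full window are excluded and logged, never silently
#' dropped. When `baseline_ms` is given, the per-epoch per-channel mean over
#' that window is subtracted.
#'
#' @param raw A `gng_raw` recording.
#' @param window_ms Two-element window around the response (default
#'   `c(-450, 550)`).
#' @param baseline_ms Optional two-element baseline window (e.g.
#'   `c(-450, -50)`).
#' @param events Events tibble; defaults to `raw$events`.
#' @return A `gng_epochs` object: `data` (epochs x channels x samples
#'   array), `time_ms`, `channels`, `fs`, `info` (event rows retained),
#'   `rejected` (all `FALSE` initially), `dropped` (log of edge-excluded
#'   events).
#' @export
segment_epochs <- function(raw, window_ms = c(-450, 550), baseline_ms = NULL,
                           events = NULL) {
  stopifnot(inherits(raw, "gng_raw"))
  events <- if (is.null(events)) raw$events else events
  fs <- raw$fs
  k0 <- ms_to_samples(window_ms[1], fs)
  k1 <- ms_to_samples(window_ms[2], fs)
  time_ms <- samples_to_ms(k0:k1, fs)
  n <- nrow(raw$data)

  lo <- events$sample + k0
  hi <- events$sample + k1
  ok <- lo >= 1L & hi <= n
  dropped <- dplyr::mutate(events[!ok, , drop = FALSE], reason = "edge")
  kept <- events[ok, , drop = FALSE]

  n_ep <- nrow(kept)
  n_ch <- length(raw$channels)
  n_sa <- length(time_ms)
  data <- array(NA_real_, dim = c(n_ep, n_ch, n_sa))
  for (i in seq_len(n_ep)) {
    data[i, , ] <- t(raw$data[seq.int(lo[ok][i], hi[ok][i]), , drop = FALSE])
  }

  ep <- structure(
    list(data = data, time_ms = time_ms, channels = raw$channels, fs = fs,
      info = tibble::as_tibble(kept), rejected = rep(FALSE, n_ep),
      dropped = tibble::as_tibble(dropped), subject = raw$subject),
    class = "gng_epochs"
  )
  if (!is.null(baseline_ms)) ep <- baseline_correct(ep, baseline_ms)
  ep
}

#' @rdname segment_epochs
#' @param epochs A `gng_epochs` object.
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-450, -50)) {
  idx <- window_index(epochs$time_ms, baseline_ms)
  if (dim(epochs$data)[1] > 0) {
    bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
    epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  }
  epochs
}

#' Amplitude-threshold epoch rejection
#'
#' Flags an epoch as rejected iff any channel sample exceeds the threshold
#' in absolute value (default +/-110 uV). Flags accumulate (logical OR with
#' any existing mask); epochs are never removed from the array.
#'
#' @param epochs A `gng_epochs` object.
#' @param threshold_uv Rejection threshold (default 110).
#' @return The epochs with an updated `rejected` mask.
#' @export
reject_epochs <- function(epochs, threshold_uv = 110) {
  stopifnot(inherits(epochs, "gng_epochs"))
  if (dim(epochs$data)[1] > 0) {
    hit <- apply(abs(epochs$data) > threshold_uv, 1, any)
    epochs$rejected <- epochs$rejected | hit
  }
  epochs
}

#' Pseudo-average re-referencing
#'
#' Subtracts, at every sample, the mean of six symmetrically distributed
#' electrodes (O1, O2, T7, T8, AF3, AF4 by default) from every channel.
#' Works on continuous recordings and on epoch sets.
#'
#' @param x A `gng_raw` or `gng_epochs` object.
#' @param ref_channels Reference channel labels; all must be present.
#' @return The re-referenced object.
#' @export
pseudo_average_reference <- function(x, ref_channels = DEFAULT_REFERENCE) {
  missing <- setdiff(ref_channels, x$channels)
  if (length(missing)) {
    abort(sprintf("Reference channels absent: %s", paste(missing, collapse = ", ")),
      class = "gng_configuration_error")
  }
  ref_idx <- match(ref_channels, x$channels)
  if (inherits(x, "gng_raw")) {
    ref <- rowMeans(x$data[, ref_idx, drop = FALSE])
    x$data <- x$data - ref
  } else if (inherits(x, "gng_epochs")) {
    if (dim(x$data)[1] > 0) {
      ref <- apply(x$data[, ref_idx, , drop = FALSE], c(1, 3), mean)
      n_ch <- dim(x$data)[2]
      x$data <- x$data - aperm(array(ref, dim = c(dim(x$data)[1], dim(x$data)[3], n_ch)),
        c(1, 3, 2))
    }
  } else {
    abort("`x` must be gng_raw or gng_epochs.", class = "gng_parameter_error")
  }
  x
}

#' Region-of-interest waveform
#'
#' Averages the selected epochs over the ROI channels (F3/F4 by default),
#' then over epochs; channel and epoch averaging commute. Rejected epochs
#' are excluded unless a `keep` mask is supplied explicitly.
#'
#' @param epochs A `gng_epochs` object.
#' @param roi ROI channel labels (default `c("F3", "F4")`).
#' @param keep Logical epoch mask; default `!epochs$rejected`. Combine with
#'   condition selections, e.g.
#'   `keep = !rejected & info$outcome == "false_alarm"`.
#' @param condition Optional label stored on the result.
#' @return A `gng_roi` tibble (`time_ms`, `value`) with attributes
#'   `n_epochs`, `condition`, `unit`; `NULL` (with a message) when no epoch
#'   is retained.
#' @export
roi_waveform <- function(epochs, roi = DEFAULT_ROI, keep = NULL, condition = NULL) {
  stopifnot(inherits(epochs, "gng_epochs"))
  if (is.null(keep)) keep <- !epochs$rejected
  roi_idx <- match(roi, epochs$channels)
  if (anyNA(roi_idx)) {
    abort("ROI channels absent from epochs.", class = "gng_configuration_error")
  }
  if (!any(keep)) {
    message("No retained epochs for condition ", condition %||% "<unnamed>")
    return(NULL)
  }
  sel <- epochs$data[keep, roi_idx, , drop = FALSE]
  value <- apply(sel, 3, mean)
  new_gng_roi(epochs$time_ms, value, n_epochs = sum(keep),
    condition = condition, unit = "uV")
}

new_gng_roi <- function(time_ms, value, n_epochs, condition = NULL, unit = "uV") {
  stopifnot(n_epochs >= 1)
  out <- tibble::tibble(time_ms = time_ms, value = value)
  structure(out, n_epochs = n_epochs, condition = condition, unit = unit,
    class = c("gng_roi", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Response-locked ERP preprocessing chain
#'
#' Fixed pipeline order for amplitude analyses: FIR bandpass (0.5-30 Hz) on
#' the continuous signal, artifact-component removal, response-locked
#' segmentation with baseline subtraction, pseudo-average re-referencing,
#' then amplitude rejection. Condition-specific ROI waveforms are extracted
#' afterwards with [roi_waveform()].
#'
#' @param raw A `gng_raw` recording.
#' @param config An [analysis_config()] list.
#' @return A `gng_epochs` object carrying the rejection mask, plus the ICA
#'   removal report in attribute `ica_report`.
#' @export
preprocess_erp <- function(raw, config = analysis_config()) {
  filt <- fir_bandpass(raw, config$erp_band_hz[1], config$erp_band_hz[2])
  if (isTRUE(config$run_ica)) {
    cleaned <- remove_artifact_components(filt, reference = raw$blink_ref,
      r_threshold = config$ica_r_threshold, seed = config$ica_seed)
    filt <- cleaned$raw
    report <- cleaned$report
  } else {
    report <- NULL
  }
  ep <- segment_epochs(filt, config$epoch_window_ms, config$erp_baseline_ms)
  ep <- pseudo_average_reference(ep, config$reference_channels)
  ep <- reject_epochs(ep, config$reject_threshold_uv)
  attr(ep, "ica_report") <- report
  ep
}
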