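# Analytic signal per column via the FFT method: positive frequencies
# doubled, negatives zeroed. The envelope is Mod(analytic).
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  mvfft(mvfft(x) * h, inverse = TRUE) / n
}

#' Band power through a 1 Hz Hilbert filter bank
#'
#' Implements the narrowband-envelope estimate of instantaneous power: the
#' band `[band_lo, band_hi]` is partitioned into `bin_width`-Hz FIR bins,
#' each bin is filtered (same windowed-sinc family as the broadband
#' filters), the analytic-signal envelope is computed per bin, and power
#' (envelope squared, uV^2) is averaged across bins. Computed on the
#' continuous, component-cleaned, re-referenced signal *before*
#' segmentation, so epoch edges never truncate the envelope.
#'
#' Bin partition: with `edges = "within"` (default) only bins fully inside
#' the band are used — theta 4-7 Hz gives `[4,5) [5,6) [6,7)`; with
#' `edges = "inclusive"` the bin starting at `band_hi` is included too.
#'
#' @param raw A `gng_raw` recording (or a samples x channels matrix with
#'   `fs` supplied).
#' @param band_lo,band_hi Band edges in Hz; must lie within \[1, 30\].
#' @param bin_width Filter-bank bin width (default 1 Hz).
#' @param edges Bin-edge convention (see above).
#' @param fs Sampling rate, only needed for matrix input.
#' @return For `gng_raw` input, a `gng_raw`-like object whose `data` holds
#'   instantaneous band power (uV^2) with attribute `band`; for matrix
#'   input, the power matrix.
#' @export
hilbert_band_power <- function(raw, band_lo = 4, band_hi = 7, bin_width = 1,
                               edges = c("within", "inclusive"), fs = NULL) {
  edges <- match.arg(edges)
  if (band_lo < 1 || band_hi > 30 || band_lo >= band_hi) {
    abort("Band must satisfy 1 <= lo < hi <= 30 Hz.", class = "gng_parameter_error")
  }
  is_raw <- inherits(raw, "gng_raw")
  x <- if (is_raw) raw$data else as.matrix(raw)
  fs <- if (is_raw) raw$fs else fs
  if (is.null(fs)) abort("`fs` required for matrix input.", class = "gng_parameter_error")

  starts <- if (edges == "within") {
    seq(band_lo, band_hi - bin_width, by = bin_width)
  } else {
    seq(band_lo, band_hi, by = bin_width)
  }
  power <- matrix(0, nrow(x), ncol(x))
  for (s in starts) {
    h <- design_fir_bandpass(s, s + bin_width, fs)
    nb <- apply_fir_zero_phase(x, h)
    power <- power + Mod(analytic_signal(nb))^2
  }
  power <- power / length(starts)

  if (is_raw) {
    raw$data <- power
    attr(raw, "band") <- c(band_lo, band_hi)
    attr(raw, "bins") <- starts
    raw
  } else {
    structure(power, band = c(band_lo, band_hi), bins = starts)
  }
}

#' Decibel baseline normalization on trial-average power
#'
#' Averages instantaneous power across the retained epochs *first*, then
#' converts to decibels against the mean of the trial-average power over the
#' baseline window: `dB(t) = 10 log10(P(t) / baseline)`, per channel.
#' Normalizing the trial average (rather than averaging per-trial dB) is
#' deliberate and order-sensitive on heterogeneous trials.
#'
#' @param power_epochs A `gng_epochs` object holding band power (uV^2).
#' @param baseline_ms Baseline window (default `c(-450, -350)` ms).
#' @param keep Logical epoch mask; default `!power_epochs$rejected`.
#' @return A `gng_ersp` object: `time_ms`, `db` (channels x samples matrix),
#'   `channels`, `n_epochs`, `baseline_ms`.
#' @export
db_normalize_trial_average <- function(power_epochs, baseline_ms = c(-450, -350),
                                       keep = NULL) {
  stopifnot(inherits(power_epochs, "gng_epochs"))
  if (is.null(keep)) keep <- !power_epochs$rejected
  if (!any(keep)) {
    message("No retained epochs for dB normalization")
    return(NULL)
  }
  pbar <- apply(power_epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  idx <- window_index(power_epochs$time_ms, baseline_ms)
  base <- rowMeans(pbar[, idx, drop = FALSE])
  if (any(base <= 0)) {
    abort("Zero baseline power: degenerate input.", class = "gng_data_error")
  }
  structure(
    list(time_ms = power_epochs$time_ms, db = 10 * log10(pbar / base),
      channels = power_epochs$channels, n_epochs = sum(keep),
      baseline_ms = baseline_ms),
    class = "gng_ersp"
  )
}

#' @rdname db_normalize_trial_average
#' @param ersp A `gng_ersp` object.
#' @param roi ROI channel labels.
#' @param condition Optional label for the resulting series.
#' @return `ersp_roi()`: a `gng_roi` tibble in dB.
#' @export
ersp_roi <- function(ersp, roi = DEFAULT_ROI, condition = NULL) {
  stopifnot(inherits(ersp, "gng_ersp"))
  roi_idx <- match(roi, ersp$channels)
  if (anyNA(roi_idx)) {
    abort("ROI channels absent.", class = "gng_configuration_error")
  }
  new_gng_roi(ersp$time_ms, colMeans(ersp$db[roi_idx, , drop = FALSE]),
    n_epochs = ersp$n_epochs, condition = condition, unit = "dB")
}

#' Theta ERSP preprocessing chain
#'
#' Fixed pipeline order for time-frequency analyses: broadband FIR filter,
#' artifact-component removal, pseudo-average re-referencing on the
#' continuous signal, 1 Hz Hilbert filter-bank band power (theta 4-7 Hz by
#' default), then response-locked segmentation. The amplitude-epoch
#' rejection mask from [preprocess_erp()] is reused (`amplitude_epochs`), so
#' both paths exclude the same trials.
#'
#' @param raw A `gng_raw` recording.
#' @param config An [analysis_config()] list.
#' @param amplitude_epochs Optional `gng_epochs` from [preprocess_erp()]
#'   whose rejection mask should be copied (matched by event order).
#' @return A `gng_epochs` object holding band power, with the rejection
#'   mask applied. Normalize per condition with
#'   [db_normalize_trial_average()].
#' @export
preprocess_ersp <- function(raw, config = analysis_config(),
                            amplitude_epochs = NULL) {
  filt <- fir_bandpass(raw, config$erp_band_hz[1], config$erp_band_hz[2])
  if (isTRUE(config$run_ica)) {
    filt <- remove_artifact_components(filt, reference = raw$blink_ref,
      r_threshold = config$ica_r_threshold, seed = config$ica_seed)$raw
  }
  filt <- pseudo_average_reference(filt, config$reference_channels)
  pow <- hilbert_band_power(filt, config$theta_band_hz[1], config$theta_band_hz[2],
    bin_width = config$filterbank_bin_hz, edges = config$theta_bin_edges)
  ep <- segment_epochs(pow, config$epoch_window_ms)
  if (!is.null(amplitude_epochs)) {
    key <- paste(ep$info$block, ep$info$trial)
    akey <- paste(amplitude_epochs$info$block, amplitude_epochs$info$trial)
    m <- match(key, akey)
    ep$rejected <- ep$rejected | (!is.na(m) & amplitude_epochs$rejected[m])
    ep$rejected[is.na(m)] <- TRUE   # no amplitude counterpart: not assessable
  }
  ep
}
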