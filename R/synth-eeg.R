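# Frontal-dominant channel-weight templates (volume conduction stand-in).
# Rows follow EPOC_CHANNELS order.
frontal_weights <- function(channels = EPOC_CHANNELS) {
  w <- c(AF3 = 0.6, F7 = 0.4, F3 = 1, FC5 = 0.55, T7 = 0.15, P7 = 0.1,
    O1 = 0.05, O2 = 0.05, P8 = 0.1, T8 = 0.15, FC6 = 0.55, F4 = 1,
    F8 = 0.4, AF4 = 0.6)
  unname(w[channels])
}

blink_weights <- function(channels = EPOC_CHANNELS) {
  w <- c(AF3 = 1, F7 = 0.3, F3 = 0.2, FC5 = 0.05, T7 = 0, P7 = 0, O1 = 0,
    O2 = 0, P8 = 0, T8 = 0, FC6 = 0.05, F4 = 0.2, F8 = 0.3, AF4 = 1)
  unname(w[channels])
}

# Gaussian background noise with a 1/f^exponent power spectrum, unit-variance
# shaped in the frequency domain then scaled to the requested RMS.
noise_one_over_f <- function(n, fs, exponent = 1, rms = 15) {
  nfft <- stats::nextn(n, 2)
  freqs <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  shape <- c(0, (pmax(freqs[-1], 0.5))^(-exponent / 2))  # knee at 0.5 Hz
  half <- (rnorm(nfft / 2 + 1) + 1i * rnorm(nfft / 2 + 1)) * shape
  half[1] <- 0
  half[nfft / 2 + 1] <- Re(half[nfft / 2 + 1])
  spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  x * rms / sd(x)
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
}

#' Synthesize a continuous 14-channel EEG recording for one subject
#'
#' Builds a 128 Hz (by default), 14-channel 10-20 montage recording spanning
#' the subject's session, as the sum of: (i) per-channel 1/f background
#' noise; (ii) on every responded trial, a phase-locked fronto-central
#' negative deflection peaking `ern_peak_ms` after the button press (full
#' `ern_amp_uv` on false alarms, `crn_fraction` of it on hits) followed by a
#' small positive rebound; (iii) a theta burst (4-7 Hz) with random
#' per-trial phase — non-phase-locked, so it cancels in time-domain
#' averaging — whose power increment is `theta_gain_db` on errors (scaled
#' further by the realized post-error slowing via `theta_pes_coupling`) and
#' `theta_correct_fraction` of that on hits; and (iv) blink transients on
#' AF3/AF4 at `blink_rate_hz`, with the ground-truth blink time course kept
#' as `blink_ref` for artifact-removal validation.
#'
#' The theta burst amplitude is calibrated against the realized background
#' theta-band power of the recording (measured on the generated noise at
#' F3), so `theta_gain_db` is expressed on the same dB scale the spectral
#' pipeline reports.
#'
#' @param behavior A classified behavior tibble for a single subject.
#' @param params A [synth_params()] object.
#' @param seed Integer seed; output is a pure function of
#'   `(behavior, params, seed)`.
#' @return A `gng_raw` object: list with `data` (samples x channels matrix,
#'   uV), `channels`, `fs`, `events` (response markers with trial linkage),
#'   `blink_ref`, `subject`.
#' @export
simulate_eeg <- function(behavior, params, seed) {
  stopifnot(inherits(params, "gng_params"))
  if (length(unique(behavior$subject)) != 1L) {
    abort("`behavior` must contain exactly one subject.", class = "gng_consistency_error")
  }
  need <- c("block", "trial", "stimulus", "onset_ms", "response", "rt_ms", "outcome")
  if (!all(need %in% names(behavior))) {
    abort("`behavior` is missing generator columns; run simulate_behavior() first.",
      class = "gng_consistency_error")
  }
  if (any(behavior$response & (is.na(behavior$rt_ms) | behavior$rt_ms <= 0 |
      behavior$rt_ms >= params$soa_ms))) {
    abort("Responded trials must have 0 < rt_ms < soa_ms.", class = "gng_consistency_error")
  }
  behavior <- dplyr::arrange(behavior, .data$block, .data$trial)
  fs <- params$fs
  n_ch <- length(EPOC_CHANNELS)
  dur_ms <- max(behavior$onset_ms) + params$soa_ms + params$block_gap_ms
  n <- as.integer(ceiling(dur_ms * fs / 1000))

  with_seed(seed, {
    data <- vapply(seq_len(n_ch), function(ch) {
      noise_one_over_f(n, fs, params$noise_exponent, params$noise_rms_uv)
    }, numeric(n))

    # Background theta power as the analysis pipeline will see it: the
    # pseudo-average-referenced F3 noise through the 1 Hz filter bank. The
    # burst amplitude is calibrated against this so `theta_gain_db` is the
    # observable ROI gain, accounting for reference attenuation of the
    # frontal template and for the burst occupying one filter-bank bin.
    ref_idx <- match(DEFAULT_REFERENCE, EPOC_CHANNELS)
    nprobe <- seq_len(min(n, 30 * fs))
    probe <- data[nprobe, match("F3", EPOC_CHANNELS)] -
      rowMeans(data[nprobe, ref_idx, drop = FALSE])
    p_bg <- mean(hilbert_band_power(matrix(probe, ncol = 1), 4, 7, fs = fs))
    roi_burst_scale <- 1 - mean(frontal_weights()[ref_idx])

    # Realized filter-bank gain of a unit burst as a function of its carrier
    # frequency: a 0.5 s burst is wider than a 1 Hz bin, so its band power
    # is attenuated; measuring the attenuation once (on a frequency grid)
    # lets the amplitude be set so `theta_gain_db` is what the spectral
    # pipeline actually reports.
    burst_t <- seq(-0.1, 0.4, by = 1 / fs)
    burst_env <- hann_window(length(burst_t))
    env_msq <- mean(burst_env^2)
    f_grid <- seq(4.6, 6.4, by = 0.1)
    pad <- numeric(8 * fs)
    probes <- vapply(f_grid, function(f0) {
      c(pad, burst_env * cos(2 * pi * f0 * burst_t), pad)
    }, numeric(2 * length(pad) + length(burst_t)))
    bank <- hilbert_band_power(probes, 4, 7, fs = fs)
    sup_idx <- length(pad) + seq_along(burst_t)
    g_eff <- colMeans(bank[sup_idx, , drop = FALSE]) / (env_msq / 2)

    responded <- dplyr::filter(behavior, .data$response)
    # realized slowing of the successor trial, for the theta-PES coupling
    pes_pairs <- post_slowing_pairs(behavior, "false_alarm")
    responded <- dplyr::left_join(responded,
      dplyr::select(pes_pairs, "block", "trial", "slowing_ms", "next_outcome",
        "next_responded"),
      by = c("block", "trial"))

    w_ern <- frontal_weights()
    ern_sd_s <- 0.04
    pe_sd_s <- 0.06

    events <- responded
    events$sample <- as.integer(round((responded$onset_ms + responded$rt_ms) *
      fs / 1000)) + 1L

    for (i in seq_len(nrow(responded))) {
      s0 <- events$sample[i]
      is_err <- responded$outcome[i] == "false_alarm"

      # phase-locked ERN (+ small positive rebound), evoked on every response
      amp <- params$ern_amp_uv * if (is_err) 1 else params$crn_fraction
      if (amp != 0) {
        k <- seq.int(-round(0.1 * fs), round(0.45 * fs))
        t_s <- k / fs
        wave <- -amp * exp(-(t_s - params$ern_peak_ms / 1000)^2 / (2 * ern_sd_s^2)) +
          0.35 * amp * exp(-(t_s - 0.25)^2 / (2 * pe_sd_s^2))
        idx <- s0 + k
        ok <- idx >= 1L & idx <= n
        data[idx[ok], ] <- data[idx[ok], ] + outer(wave[ok], w_ern)
      }

      # induced theta burst with random phase
      gain_db <- if (is_err) {
        g <- params$theta_gain_db
        if (!is.na(responded$slowing_ms[i])) {
          g <- g + params$theta_pes_coupling *
            (responded$slowing_ms[i] - params$pes_shift_ms) / 100
        }
        max(g, 0)
      } else {
        max(params$theta_correct_fraction * params$theta_gain_db, 0)
      }
      if (gain_db > 0 && p_bg > 0) {
        ratio <- 10^(gain_db / 10)
        f0 <- runif(1, 4.6, 6.4)
        g0 <- stats::approx(f_grid, g_eff, xout = f0, rule = 2)$y
        a <- sqrt((ratio - 1) * p_bg / (g0 * env_msq / 2)) / roi_burst_scale
        phi <- runif(1, 0, 2 * pi)
        burst <- a * burst_env * cos(2 * pi * f0 * burst_t + phi)
        idx <- s0 + seq.int(round(-0.1 * fs), length.out = length(burst_t))
        ok <- idx >= 1L & idx <= n
        data[idx[ok], ] <- data[idx[ok], ] + outer(burst[ok], w_ern)
      }
    }

    # blinks: Poisson-timed raised-cosine lobes on AF3/AF4 (+ spill-over)
    blink_ref <- numeric(n)
    n_blinks <- rpois(1, params$blink_rate_hz * n / fs)
    if (n_blinks > 0 && params$blink_amp_uv > 0) {
      lobe <- hann_window(round(0.4 * fs))
      w_blink <- blink_weights()
      starts <- sort(sample.int(n - length(lobe), n_blinks, replace = TRUE))
      for (s in starts) {
        idx <- s + seq_along(lobe) - 1L
        blink_ref[idx] <- blink_ref[idx] + lobe
        data[idx, ] <- data[idx, ] + params$blink_amp_uv * outer(lobe, w_blink)
      }
    }

    new_gng_raw(
      data = data, channels = EPOC_CHANNELS, fs = fs,
      events = dplyr::select(events, "sample", "block", "trial", "stimulus",
        "outcome", "rt_ms", "slowing_ms", "next_outcome", "next_responded"),
      blink_ref = blink_ref,
      subject = behavior$subject[1]
    )
  })
}

new_gng_raw <- function(data, channels, fs, events, blink_ref = NULL, subject = NA) {
  if (ncol(data) != length(channels)) {
    abort("Channel count mismatch.", class = "gng_consistency_error")
  }
  if (nrow(events) && (any(events$sample < 1L) || any(events$sample > nrow(data)))) {
    abort("Event samples outside recording bounds.", class = "gng_consistency_error")
  }
  structure(
    list(data = data, channels = channels, fs = fs, events = events,
      blink_ref = blink_ref, subject = subject),
    class = "gng_raw"
  )
}

#' @export
print.gng_raw <- function(x, ...) {
  cat(sprintf("<gng_raw> subject %s: %d channels x %d samples @ %g Hz (%.1f s), %d response events\n",
    format(x$subject), length(x$channels), nrow(x$data), x$fs,
    nrow(x$data) / x$fs, nrow(x$events)))
  invisible(x)
}
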