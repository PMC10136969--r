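#' Parameters for the synthetic go/no-go cohort generator
#'
#' Bundles every tunable of the simulator: task design, reaction-time (RT)
#' dynamics, post-error behavioral effects, and the EEG forward model.
#' Defaults reproduce the study conditions the pipeline is designed for:
#' 90-trial blocks with P(go) = 0.7 and a 1200 ms onset-to-onset cadence
#' (400 ms stimulus + 800 ms fixation cross), a commission-error rate near
#' 36% with error responses faster than correct ones, a hit rate near 74%,
#' ~150 ms of post-error slowing coupled to post-error accuracy, a
#' response-locked frontal error negativity, and a non-phase-locked theta
#' (4-7 Hz) power increase on errors that scales with subsequent slowing.
#'
#' @section RT model:
#' Reaction times follow a lognormal model with a slowly drifting
#' within-subject "speed state": for subject *j* and trial *t*,
#' `log RT = mu_j + x_t + nu_t`, where `x_t` is a stationary AR(1) process
#' (autocorrelation `rt_ar`, stationary SD `rt_correct_spread`) and `nu_t`
#' is small independent motor noise. Commission errors are emitted
#' preferentially in fast states through a logistic tilt on the state, with
#' the tilt strength calibrated numerically so that the median commission RT
#' matches `rt_error_median_ms` while the marginal commission probability
#' stays exactly `p_commission`. Because errors are fast *states* rather
#' than draws from a shifted distribution, the trial that follows an error
#' starts from (almost) the same speed state, so the raw single-trial
#' post-error slowing equals the injected `pes_shift_ms` rather than being
#' inflated by regression toward the mean.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param blocks_per_subject Blocks completed per subject; a single count or
#'   an integer range to sample from uniformly (default `3:8`).
#' @param trials_per_block Trials per block (default 90).
#' @param p_go Probability of a go stimulus (default 0.70).
#' @param soa_ms Onset-to-onset interval in ms (default 1200; 400 ms stimulus
#'   + 800 ms cross).
#' @param rt_correct_median_ms Median correct-trial RT in ms (default 587).
#' @param rt_correct_spread Within-subject lognormal spread (SD of the latent
#'   log-speed state; default 0.28).
#' @param rt_error_median_ms Target median commission-error RT in ms
#'   (default 481; must not exceed `rt_correct_median_ms`).
#' @param rt_error_spread Extra lognormal noise on commission RTs
#'   (default 0.05).
#' @param p_commission Probability of responding on a no-go trial
#'   (default 0.36).
#' @param p_omission Probability of not responding on a go trial
#'   (default 0.26).
#' @param pes_shift_ms Additive RT increment on the trial following a
#'   responded false alarm, in ms (default 150).
#' @param pes_shift_sd_ms SD of the trial-to-trial noise on that increment
#'   (default 80).
#' @param pea_coupling Logistic slope linking next-trial response
#'   probabilities to realized slowing, in logit units per 100 ms of slowing
#'   relative to `pes_shift_ms` (default 0.6; 0 disables the coupling).
#' @param rt_ar Lag-1 autocorrelation of the latent speed state
#'   (default 0.995).
#' @param rt_motor_spread SD of the independent motor noise on log RT
#'   (default 0.03).
#' @param rt_subject_spread Between-subject SD of median log RT
#'   (default 0.10).
#' @param ern_amp_uv Peak amplitude (uV) of the phase-locked error negativity
#'   added on false alarms (default 6).
#' @param crn_fraction Fraction of `ern_amp_uv` applied on correct responses
#'   (default 0.25).
#' @param ern_peak_ms Latency of the negative peak after the response
#'   (default 70 ms).
#' @param theta_gain_db Induced theta power increment on errors, in dB over
#'   the background theta level (default 3).
#' @param theta_correct_fraction Fraction of `theta_gain_db` applied on
#'   correct responses (default 0.3).
#' @param theta_pes_coupling Scaling of error-trial theta by subsequent
#'   realized slowing, in dB per 100 ms of slowing relative to
#'   `pes_shift_ms` (default 1.5).
#' @param noise_exponent Spectral slope of the 1/f background (default 1).
#' @param noise_rms_uv RMS amplitude of the background noise per channel
#'   (default 15 uV).
#' @param blink_rate_hz Rate of blink transients on AF3/AF4 (default 0.05).
#' @param blink_amp_uv Blink peak amplitude (default 150 uV).
#' @param fs Sampling rate in Hz (default 128).
#'
#' @return An object of class `gng_params` (a validated named list).
#' @examples
#' p <- synth_params(n_subjects = 4, blocks_per_subject = 2)
#' p$p_go
#' @export
synth_params <- function(n_subjects = 30,
                         blocks_per_subject = 3:8,
                         trials_per_block = 90,
                         p_go = 0.70,
                         soa_ms = 1200,
                         rt_correct_median_ms = 587,
                         rt_correct_spread = 0.28,
                         rt_error_median_ms = 481,
                         rt_error_spread = 0.05,
                         p_commission = 0.36,
                         p_omission = 0.26,
                         pes_shift_ms = 150,
                         pes_shift_sd_ms = 80,
                         pea_coupling = 0.6,
                         rt_ar = 0.995,
                         rt_motor_spread = 0.03,
                         rt_subject_spread = 0.10,
                         ern_amp_uv = 6,
                         crn_fraction = 0.25,
                         ern_peak_ms = 70,
                         theta_gain_db = 3,
                         theta_correct_fraction = 0.3,
                         theta_pes_coupling = 1.5,
                         noise_exponent = 1,
                         noise_rms_uv = 15,
                         blink_rate_hz = 0.05,
                         blink_amp_uv = 150,
                         fs = 128) {
  assert_probability(p_go, "p_go")
  assert_probability(p_commission, "p_commission")
  assert_probability(p_omission, "p_omission")
  assert_positive(n_subjects, "n_subjects")
  assert_positive(trials_per_block, "trials_per_block")
  assert_positive(soa_ms, "soa_ms")
  assert_positive(rt_correct_median_ms, "rt_correct_median_ms")
  assert_positive(rt_error_median_ms, "rt_error_median_ms")
  assert_positive(fs, "fs")
  if (any(blocks_per_subject < 1)) {
    abort("`blocks_per_subject` must be >= 1.", class = "gng_parameter_error")
  }
  if (rt_error_median_ms > rt_correct_median_ms) {
    abort("`rt_error_median_ms` must not exceed `rt_correct_median_ms` (errors are fast).",
      class = "gng_parameter_error")
  }
  if (rt_ar < 0 || rt_ar >= 1) {
    abort("`rt_ar` must be in [0, 1).", class = "gng_parameter_error")
  }
  # RTs above soa_ms are censored to non-responses; the design must leave
  # headroom over plausible RTs or responses would be lost wholesale.
  if (soa_ms < 1.5 * rt_correct_median_ms) {
    abort("`soa_ms` must exceed the plausible RT range (>= 1.5 x correct median).",
      class = "gng_parameter_error")
  }

  p <- list(
    n_subjects = as.integer(n_subjects),
    blocks_per_subject = as.integer(blocks_per_subject),
    trials_per_block = as.integer(trials_per_block),
    p_go = p_go, soa_ms = soa_ms,
    rt_correct_median_ms = rt_correct_median_ms,
    rt_correct_spread = rt_correct_spread,
    rt_error_median_ms = rt_error_median_ms,
    rt_error_spread = rt_error_spread,
    p_commission = p_commission, p_omission = p_omission,
    pes_shift_ms = pes_shift_ms, pes_shift_sd_ms = pes_shift_sd_ms,
    pea_coupling = pea_coupling,
    rt_ar = rt_ar, rt_motor_spread = rt_motor_spread,
    rt_subject_spread = rt_subject_spread,
    ern_amp_uv = ern_amp_uv, crn_fraction = crn_fraction,
    ern_peak_ms = ern_peak_ms,
    theta_gain_db = theta_gain_db,
    theta_correct_fraction = theta_correct_fraction,
    theta_pes_coupling = theta_pes_coupling,
    noise_exponent = noise_exponent, noise_rms_uv = noise_rms_uv,
    blink_rate_hz = blink_rate_hz, blink_amp_uv = blink_amp_uv,
    fs = fs,
    block_gap_ms = 2000
  )
  structure(p, class = "gng_params")
}

#' @export
print.gng_params <- function(x, ...) {
  cat("<gng_params> synthetic go/no-go cohort parameters\n")
  cat(sprintf("  %d subjects, blocks %s, %d trials/block, P(go)=%.2f, SOA %g ms\n",
    x$n_subjects, paste(range(x$blocks_per_subject), collapse = "-"),
    x$trials_per_block, x$p_go, x$soa_ms))
  cat(sprintf("  RT: correct %g ms / error %g ms, PES shift %g ms, PEA coupling %g\n",
    x$rt_correct_median_ms, x$rt_error_median_ms, x$pes_shift_ms, x$pea_coupling))
  cat(sprintf("  EEG: ERN %g uV, theta %g dB (coupling %g dB/100ms), fs %g Hz\n",
    x$ern_amp_uv, x$theta_gain_db, x$theta_pes_coupling, x$fs))
  invisible(x)
}

# Calibrate the logistic state tilt for commission errors.
#
# Commission probability on no-go trials is plogis(a - k * z) where z is the
# standardized latent speed state. Given the marginal rate p_c and a target
# median state shift (log rt_error_median - log rt_correct_median), solve for
# (a, k) numerically: `a` keeps the marginal exactly p_c for a given k, and
# `k` is chosen so the median state among commissions hits the target. If the
# target shift exceeds what state selection can produce (hard-threshold
# limit), the remainder is returned as a deterministic log offset.
calibrate_commission <- function(p_commission, target_log_shift, sigma_x) {
  z <- seq(-6, 6, by = 0.005)
  phi <- dnorm(z)
  phi <- phi / sum(phi)
  if (p_commission <= 0 || p_commission >= 1 || target_log_shift >= 0 || sigma_x <= 0) {
    return(list(a = qlogis(max(min(p_commission, 1 - 1e-12), 1e-12)), k = 0,
      residual_log_offset = min(target_log_shift, 0)))
  }
  solve_a <- function(k) {
    uniroot(function(a) sum(phi * plogis(a - k * z)) - p_commission,
      lower = -40, upper = 40, tol = 1e-10)$root
  }
  med_shift <- function(k) {
    a <- solve_a(k)
    w <- phi * plogis(a - k * z)
    cw <- cumsum(w) / sum(w)
    sigma_x * z[which.min(abs(cw - 0.5))]
  }
  k_hi <- 25
  if (med_shift(k_hi) > target_log_shift) {
    # even near-threshold selection cannot reach the target median; absorb
    # the remainder into a deterministic offset on commission RTs
    k <- k_hi
    resid <- target_log_shift - med_shift(k_hi)
  } else {
    k <- uniroot(function(k) med_shift(k) - target_log_shift,
      lower = 1e-3, upper = k_hi, tol = 1e-6)$root
    resid <- 0
  }
  list(a = solve_a(k), k = k, residual_log_offset = resid)
}
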