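#' Simulate behavioral responses for a trial sequence
#'
#' Adds per-trial response flags and reaction times to a task sequence under
#' the latent-speed RT model described in [synth_params()]. Go trials are
#' responded with probability `1 - p_omission`; no-go trials with marginal
#' probability `p_commission`, tilted toward fast speed states so commission
#' RTs are faster than correct RTs. The trial that immediately follows a
#' responded false alarm receives an additive RT increment of
#' `pes_shift_ms` (plus noise), and its response probabilities are modulated
#' by the realized slowing through a logistic link with slope
#' `pea_coupling` (more slowing, more likely a hit; less likely a new false
#' alarm). Responses that would land at or after the next stimulus onset
#' (`rt >= soa_ms`) are censored to non-responses. Outcomes are classified
#' with [classify_outcomes()].
#'
#' @param sequence A tibble from [simulate_task_sequence()].
#' @param params A [synth_params()] object.
#' @param seed Integer seed; output is a pure function of
#'   `(sequence, params, seed)`.
#' @return The sequence tibble with added columns `response` (logical),
#'   `rt_ms` (NA when unresponded) and `outcome`.
#' @examples
#' p <- synth_params(n_subjects = 2, blocks_per_subject = 2)
#' beh <- simulate_behavior(simulate_task_sequence(p, 1), p, seed = 2)
#' table(beh$outcome)
#' @export
simulate_behavior <- function(sequence, params, seed) {
  stopifnot(inherits(params, "gng_params"))
  if (nrow(sequence) == 0L) {
    return(dplyr::mutate(sequence, response = logical(0), rt_ms = numeric(0),
      outcome = character(0)))
  }
  req <- c("subject", "block", "trial", "stimulus")
  if (!all(req %in% names(sequence))) {
    abort("`sequence` must have columns subject/block/trial/stimulus.",
      class = "gng_data_error")
  }

  sigma_x <- params$rt_correct_spread
  cal <- calibrate_commission(
    params$p_commission,
    log(params$rt_error_median_ms / params$rt_correct_median_ms),
    sigma_x
  )

  out <- with_seed(seed, {
    sequence <- dplyr::arrange(sequence, .data$subject, .data$block, .data$trial)
    parts <- split(sequence, sequence$subject)
    res <- lapply(parts, function(tr) {
      simulate_behavior_subject(tr, params, cal)
    })
    dplyr::bind_rows(res)
  })
  classify_outcomes(out)
}

# One subject: vector draws first, then a sequential within-block pass that
# applies the post-error shift and the accuracy coupling.
simulate_behavior_subject <- function(tr, params, cal) {
  n <- nrow(tr)
  sigma_x <- params$rt_correct_spread
  mu <- log(params$rt_correct_median_ms) + rnorm(1, 0, params$rt_subject_spread)
  rho <- params$rt_ar

  # stationary AR(1) latent speed state, restarted at each block boundary
  innov_sd <- sigma_x * sqrt(1 - rho^2)
  x <- numeric(n)
  new_block <- c(TRUE, tr$block[-1] != tr$block[-n])
  for (i in seq_len(n)) {
    x[i] <- if (new_block[i]) rnorm(1, 0, sigma_x) else rho * x[i - 1] + rnorm(1, 0, innov_sd)
  }
  nu <- rnorm(n, 0, params$rt_motor_spread)
  err_extra <- rnorm(n, 0, params$rt_error_spread)
  u_resp <- runif(n)                  # response decision
  shift_noise <- rnorm(n, 0, params$pes_shift_sd_ms)

  go <- tr$stimulus == "go"
  base_go_logit <- qlogis(min(max(1 - params$p_omission, 1e-12), 1 - 1e-12))
  base_nogo_logit <- cal$a - cal$k * (x / sigma_x)

  response <- logical(n)
  rt <- rep(NA_real_, n)
  prev_fa_rt <- NA_real_              # set when previous trial was a responded FA

  for (i in seq_len(n)) {
    if (new_block[i]) prev_fa_rt <- NA_real_
    post_error <- !is.na(prev_fa_rt)

    base_rt <- exp(mu + x[i] + nu[i] +
      (if (!go[i]) cal$residual_log_offset + err_extra[i] else 0))
    slowing <- NA_real_
    if (post_error) {
      base_rt <- base_rt + params$pes_shift_ms + shift_noise[i]
      slowing <- base_rt - prev_fa_rt
    }

    logit <- if (go[i]) base_go_logit else base_nogo_logit[i]
    if (post_error && params$pea_coupling != 0) {
      mod <- params$pea_coupling * (slowing - params$pes_shift_ms) / 100
      logit <- logit + if (go[i]) mod else -mod
    }
    responded <- u_resp[i] < plogis(logit)
    if (responded && base_rt < params$soa_ms && base_rt > 0) {
      response[i] <- TRUE
      rt[i] <- base_rt
    }
    prev_fa_rt <- if (response[i] && !go[i]) rt[i] else NA_real_
  }

  dplyr::mutate(tr, response = response, rt_ms = rt)
}
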