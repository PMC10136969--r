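#' Analysis configuration
#'
#' Collects every constant of the preprocessing and inference pipeline in
#' one place. Defaults are the study conditions the package targets:
#' 0.5-30 Hz FIR band, response-locked epochs -450..550 ms, amplitude
#' baseline \[-450, -50\] ms, dB baseline \[-450, -350\] ms, +/-110 uV
#' rejection, F3/F4 ROI, six-channel pseudo-average reference, theta 4-7 Hz,
#' test windows \[-50, 150\] ms (ERP) and \[-350, 450\] ms (ERSP), per-sample
#' alpha 0.01 with >= 5 consecutive samples, >= 7 artifact-free error trials
#' (per tertile where applicable), 20 RT-matching repeats, tertile splits,
#' and Bonferroni 0.05/3 for post hocs.
#'
#' @param ... Named overrides of any default listed above.
#' @return A named list of class `gng_config`.
#' @examples
#' analysis_config(n_perm = 500)$n_perm
#' @export
analysis_config <- function(...) {
  defaults <- list(
    erp_band_hz = c(0.5, 30),
    epoch_window_ms = c(-450, 550),
    erp_baseline_ms = c(-450, -50),
    ersp_baseline_ms = c(-450, -350),
    reject_threshold_uv = 110,
    roi_channels = DEFAULT_ROI,
    reference_channels = DEFAULT_REFERENCE,
    theta_band_hz = c(4, 7),
    filterbank_bin_hz = 1,
    theta_bin_edges = "within",
    erp_test_window_ms = c(-50, 150),
    ersp_test_window_ms = c(-350, 450),
    alpha = 0.01,
    min_consec = 5,
    n_perm = 2000,
    min_error_trials = 7,
    n_match_repeats = 20,
    n_tertiles = 3,
    bonferroni_family_alpha = 0.05,
    bonferroni_m = 3,
    soa_ms = 1200,
    run_ica = TRUE,
    ica_r_threshold = 0.7,
    ica_seed = 1,
    successors = "any",
    analyses = c("A1", "A2", "A3", "A4", "A5")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config fields: %s", paste(unknown, collapse = ", ")),
      class = "gng_configuration_error")
  }
  structure(modifyList(defaults, over), class = "gng_config")
}

#' Run the full cohort analysis
#'
#' Orchestrates the five analyses over a cohort, applying the inclusion
#' rules per analysis and recomputing the subject pool for each:
#'
#' * **A1** error vs correct contrasts of the ROI ERP (window \[-50, 150\]
#'   ms) and theta ERSP (\[-350, 450\] ms) by sample-wise paired permutation
#'   t-tests; subjects need >= 7 artifact-free error epochs.
#' * **A2** successful (error then hit) vs failed (error then false alarm)
#'   recovery contrasts of the same waveforms; >= 7 artifact-free epochs per
#'   recovery condition.
#' * **A3** per-subject tertile split of error-preceding-hit trials by
#'   single-trial post-error slowing; ERN and theta waveform areas per
#'   tertile, one-way ANOVA pooled across subjects and paired-t post hocs
#'   at the Bonferroni level; >= 7 epochs per tertile.
#' * **A4** behavioral contrasts: PES vs RT-matched PCS and PEA vs matched
#'   PCA (Wilcoxon signed-rank), and PEA across PES tertiles (Friedman plus
#'   Wilcoxon post hocs); >= 7 error trials (per tertile for the tertile
#'   analysis).
#' * **A5** response-stimulus intervals across PES tertiles (Friedman plus
#'   post hocs), in the behavioral tertile pool and in the neural (A3)
#'   pool.
#'
#' All comparisons carry effect sizes `r = |stat| / sqrt(n)`.
#'
#' @param cohort A `gng_cohort` (synthetic or assembled from data).
#' @param config An [analysis_config()].
#' @param seed Master seed for the stochastic steps (permutations, RT
#'   matching); fixed seed + fixed cohort gives identical reports.
#' @return A `gng_report` list of result tibbles (see [write_report()]).
#' @export
run_analyses <- function(cohort, config = analysis_config(), seed = 1) {
  stopifnot(inherits(cohort, "gng_cohort"))
  trials <- ensure_classified(cohort$trials)
  subjects <- sort(unique(trials$subject))
  if (!length(subjects)) {
    abort("Empty cohort.", class = "gng_data_error")
  }
  an <- config$analyses
  report <- list(config = config, seed = seed, analyses = an)
  exclusions <- list()

  ## ---- behavioral layer -------------------------------------------------
  summaries <- subject_behavior_summary(trials, config$n_match_repeats,
    seed = seed + 101L, successors = config$successors)
  report$behavior_subjects <- summaries
  report$behavior_table <- cohort_behavior_table(summaries)

  beh_pool <- inclusion_filter(
    dplyr::select(summaries, "subject", n = "n_error_trials"),
    config$min_error_trials)
  exclusions$behavior <- beh_pool$log

  if ("A4" %in% an) {
    rows <- dplyr::filter(summaries, .data$subject %in% beh_pool$retained)
    a4 <- list()
    w_rt <- wilcoxon_signed_rank(rows$error_rt_ms, rows$correct_rt_ms)
    w_pes <- wilcoxon_signed_rank(rows$pes_ms, rows$matched_pcs_ms)
    w_pea <- wilcoxon_signed_rank(rows$pea_pct, rows$matched_pca_pct)
    report$a4_wilcoxon <- dplyr::bind_rows(
      dplyr::mutate(w_rt, comparison = "error_rt_vs_correct_rt", .before = 1),
      dplyr::mutate(w_pes, comparison = "pes_vs_matched_pcs", .before = 1),
      dplyr::mutate(w_pea, comparison = "pea_vs_matched_pca", .before = 1)
    )
    report$a4_wilcoxon$r <- round(effect_size_r(report$a4_wilcoxon$Z,
      report$a4_wilcoxon$n), 2)

    tert <- behavioral_tertiles(trials, subjects, config)
    exclusions$behavior_tertiles <- tert$log
    report$a4_tertile_pea <- tert$pea
    if (nrow(tert$pea) >= 2) {
      report$a4_tertile_tests <- tertile_rank_tests(tert$pea,
        c("pea_t1", "pea_t2", "pea_t3"), config)
    }
    report$a5_rsi_behavior <- tert$rsi
    if ("A5" %in% an && nrow(tert$rsi) >= 2) {
      report$a5_rsi_behavior_tests <- tertile_rank_tests(tert$rsi,
        c("rsi_t1", "rsi_t2", "rsi_t3"), config)
    }
  }

  ## ---- neural layer -----------------------------------------------------
  if (any(c("A1", "A2", "A3") %in% an)) {
    neural <- lapply(subjects, function(s) {
      subject_neural_features(cohort, s, config)
    })
    names(neural) <- as.character(subjects)

    if ("A1" %in% an) {
      r1 <- contrast_over_subjects(neural, "erp_error", "erp_correct",
        "ersp_error", "ersp_correct", config, seed + 201L,
        min_counts = c("n_error", "n_correct"))
      report$a1_erp <- r1$erp
      report$a1_ersp <- r1$ersp
      report$a1_grand <- r1$grand
      exclusions$a1 <- r1$log
    }
    if ("A2" %in% an) {
      r2 <- contrast_over_subjects(neural, "erp_success", "erp_fail",
        "ersp_success", "ersp_fail", config, seed + 301L,
        min_counts = c("n_success", "n_fail"))
      report$a2_erp <- r2$erp
      report$a2_ersp <- r2$ersp
      report$a2_grand <- r2$grand
      exclusions$a2 <- r2$log
    }
    if ("A3" %in% an) {
      r3 <- tertile_area_analysis(neural, config)
      report$a3_areas <- r3$areas
      report$a3_anova <- r3$anova
      report$a3_posthoc <- r3$posthoc
      exclusions$a3 <- r3$log
      if ("A5" %in% an && !is.null(r3$rsi) && nrow(r3$rsi) >= 2) {
        report$a5_rsi_neural <- r3$rsi
        report$a5_rsi_neural_tests <- tertile_rank_tests(r3$rsi,
          c("rsi_t1", "rsi_t2", "rsi_t3"), config)
      }
    }
  }

  report$exclusions <- exclusions
  structure(report, class = "gng_report")
}

# Tertile split of each subject's post-error pairs by single-trial slowing;
# per-tertile PEA and median RSI of the current (error) trial.
behavioral_tertiles <- function(trials, subjects, config) {
  rows_pea <- list(); rows_rsi <- list(); log <- list()
  for (s in subjects) {
    tr <- dplyr::filter(trials, .data$subject == s)
    pairs <- post_slowing_pairs(tr, "false_alarm")
    pairs <- dplyr::filter(pairs, !is.na(.data$slowing_ms))
    counts <- c(NA_integer_, NA_integer_, NA_integer_)
    ok <- nrow(pairs) >= 3 * config$min_error_trials
    if (ok) {
      ts <- tertile_split(pairs$slowing_ms)
      counts <- ts$sizes
      ok <- all(ts$sizes >= config$min_error_trials)
      if (ok) {
        pea <- vapply(1:3, function(k) {
          post_accuracy(pairs[ts$assignment == k, ])
        }, numeric(1))
        rsi <- vapply(1:3, function(k) {
          median(config$soa_ms - pairs$rt_ms[ts$assignment == k])
        }, numeric(1))
        med <- ts$medians
        rows_pea[[length(rows_pea) + 1L]] <- tibble::tibble(subject = s,
          pea_t1 = pea[1], pea_t2 = pea[2], pea_t3 = pea[3],
          pes_med_t1 = med[1], pes_med_t2 = med[2], pes_med_t3 = med[3])
        rows_rsi[[length(rows_rsi) + 1L]] <- tibble::tibble(subject = s,
          rsi_t1 = rsi[1], rsi_t2 = rsi[2], rsi_t3 = rsi[3])
      }
    }
    log[[length(log) + 1L]] <- tibble::tibble(subject = s,
      n_pairs = nrow(pairs), t1 = counts[1], t2 = counts[2], t3 = counts[3],
      retained = ok)
  }
  pea <- dplyr::bind_rows(rows_pea)
  pea <- pea[complete.cases(pea[, c("pea_t1", "pea_t2", "pea_t3")]), ]
  list(pea = pea, rsi = dplyr::bind_rows(rows_rsi), log = dplyr::bind_rows(log))
}

# Friedman + Wilcoxon post hocs (3 vs 2, 3 vs 1, 2 vs 1) over three
# per-subject tertile columns.
tertile_rank_tests <- function(df, cols, config) {
  m <- as.matrix(df[, cols])
  fr <- friedman_rank_test(m)
  ph <- lapply(list(c(3, 2), c(3, 1), c(2, 1)), function(pr) {
    w <- wilcoxon_signed_rank(m[, pr[1]], m[, pr[2]])
    dplyr::mutate(w, comparison = sprintf("t%d_vs_t%d", pr[1], pr[2]),
      r = round(effect_size_r(.data$Z, nrow(m)), 2), .before = 1)
  })
  list(
    friedman = fr,
    posthoc = dplyr::bind_rows(ph),
    bonferroni_alpha = bonferroni_alpha(config$bonferroni_family_alpha,
      config$bonferroni_m)
  )
}

# Preprocess one subject end to end and extract every condition series the
# analyses need, plus inclusion counts. The broadband filter and component
# removal are shared between the amplitude and power paths (they are the
# common head of both pipelines).
subject_neural_features <- function(cohort, s, config) {
  raw <- subject_recording(cohort, s)
  filt <- fir_bandpass(raw, config$erp_band_hz[1], config$erp_band_hz[2])
  if (isTRUE(config$run_ica)) {
    filt <- remove_artifact_components(filt, reference = raw$blink_ref,
      r_threshold = config$ica_r_threshold, seed = config$ica_seed)$raw
  }
  # amplitude path: segment + baseline, reference, reject
  ep <- segment_epochs(filt, config$epoch_window_ms, config$erp_baseline_ms)
  ep <- pseudo_average_reference(ep, config$reference_channels)
  ep <- reject_epochs(ep, config$reject_threshold_uv)
  # power path: reference the continuous signal, filter bank, segment,
  # reuse the amplitude rejection mask (same events, same window)
  refc <- pseudo_average_reference(filt, config$reference_channels)
  powc <- hilbert_band_power(refc, config$theta_band_hz[1],
    config$theta_band_hz[2], bin_width = config$filterbank_bin_hz,
    edges = config$theta_bin_edges)
  pow <- segment_epochs(powc, config$epoch_window_ms)
  stopifnot(nrow(pow$info) == nrow(ep$info))
  pow$rejected <- pow$rejected | ep$rejected
  info <- ep$info
  kept <- !ep$rejected

  is_err <- info$outcome == "false_alarm"
  is_hit <- info$outcome == "hit"
  succ <- is_err & !is.na(info$next_outcome) & info$next_outcome == "hit"
  fail <- is_err & !is.na(info$next_outcome) & info$next_outcome == "false_alarm"

  roi <- config$roi_channels
  erp_series <- function(sel, tag) {
    roi_waveform(ep, roi, keep = kept & sel, condition = tag)
  }
  ersp_series <- function(sel, tag) {
    # the ERSP path has its own epoch set (same events); map the selection
    key <- paste(info$block, info$trial)
    pkey <- paste(pow$info$block, pow$info$trial)
    psel <- pkey %in% key[kept & sel]
    if (!any(psel & !pow$rejected)) return(NULL)
    db <- db_normalize_trial_average(pow, config$ersp_baseline_ms,
      keep = psel & !pow$rejected)
    if (is.null(db)) NULL else ersp_roi(db, roi, condition = tag)
  }

  feats <- list(
    subject = s,
    n_error = sum(kept & is_err), n_correct = sum(kept & is_hit),
    n_success = sum(kept & succ), n_fail = sum(kept & fail),
    erp_error = erp_series(is_err, "error"),
    erp_correct = erp_series(is_hit, "correct"),
    ersp_error = ersp_series(is_err, "error"),
    ersp_correct = ersp_series(is_hit, "correct"),
    erp_success = erp_series(succ, "success"),
    erp_fail = erp_series(fail, "fail"),
    ersp_success = ersp_series(succ, "success"),
    ersp_fail = ersp_series(fail, "fail")
  )

  # A3: tertiles of retained error-preceding-hit epochs by realized slowing
  sel3 <- which(kept & succ & !is.na(info$slowing_ms))
  feats$tertiles <- NULL
  if (length(sel3) >= 3 * config$min_error_trials) {
    ts <- tertile_split(info$slowing_ms[sel3])
    if (all(ts$sizes >= config$min_error_trials)) {
      per_t <- lapply(1:3, function(k) {
        idx <- sel3[ts$assignment == k]
        selv <- logical(nrow(info)); selv[idx] <- TRUE
        list(
          erp = erp_series(selv, sprintf("tertile%d", k)),
          ersp = ersp_series(selv, sprintf("tertile%d", k)),
          rsi = median(config$soa_ms - info$rt_ms[idx]),
          pes_med = median(info$slowing_ms[idx])
        )
      })
      feats$tertiles <- per_t
    }
  }
  feats
}

# Stack per-subject condition series into matrices and run the two
# permutation contrasts; subjects must pass every count in `min_counts`.
contrast_over_subjects <- function(neural, erp_a, erp_b, ersp_a, ersp_b,
                                   config, seed, min_counts) {
  counts <- dplyr::bind_rows(lapply(neural, function(f) {
    tibble::tibble(subject = f$subject, a = f[[min_counts[1]]], b = f[[min_counts[2]]])
  }))
  have <- vapply(neural, function(f) {
    !is.null(f[[erp_a]]) && !is.null(f[[erp_b]]) &&
      !is.null(f[[ersp_a]]) && !is.null(f[[ersp_b]])
  }, logical(1))
  ok <- counts$a >= config$min_error_trials & counts$b >= config$min_error_trials & have
  log <- dplyr::mutate(counts, retained = ok)
  names(log)[2:3] <- min_counts
  if (sum(ok) < 2) {
    return(list(erp = NULL, ersp = NULL, grand = NULL, log = log))
  }
  sub <- neural[ok]
  stack <- function(field) {
    do.call(rbind, lapply(sub, function(f) f[[field]]$value))
  }
  time_erp <- sub[[1]][[erp_a]]$time_ms
  time_ersp <- sub[[1]][[ersp_a]]$time_ms
  erp <- samplewise_permutation_test(stack(erp_a), stack(erp_b), time_erp,
    window_ms = config$erp_test_window_ms, alpha = config$alpha,
    min_consec = config$min_consec, n_perm = config$n_perm, seed = seed)
  ersp <- samplewise_permutation_test(stack(ersp_a), stack(ersp_b), time_ersp,
    window_ms = config$ersp_test_window_ms, alpha = config$alpha,
    min_consec = config$min_consec, n_perm = config$n_perm, seed = seed + 1L)
  grand <- list(
    erp_a = new_gng_roi(time_erp, colMeans(stack(erp_a)), sum(ok), erp_a, "uV"),
    erp_b = new_gng_roi(time_erp, colMeans(stack(erp_b)), sum(ok), erp_b, "uV"),
    ersp_a = new_gng_roi(time_ersp, colMeans(stack(ersp_a)), sum(ok), ersp_a, "dB"),
    ersp_b = new_gng_roi(time_ersp, colMeans(stack(ersp_b)), sum(ok), ersp_b, "dB")
  )
  list(erp = erp, ersp = ersp, grand = grand, log = log)
}

# A3: waveform areas per subject x tertile -> pooled one-way ANOVA and
# paired-t post hocs, for the ERN window and the theta window.
tertile_area_analysis <- function(neural, config) {
  rows <- list(); rsi_rows <- list(); log <- list()
  for (f in neural) {
    ok <- !is.null(f$tertiles)
    log[[length(log) + 1L]] <- tibble::tibble(subject = f$subject,
      n_success = f$n_success, retained = ok)
    if (!ok) next
    for (k in 1:3) {
      tk <- f$tertiles[[k]]
      if (is.null(tk$erp) || is.null(tk$ersp)) { ok <- FALSE; break }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = f$subject, tertile = k,
        ern_area = waveform_area(tk$erp, config$erp_test_window_ms),
        theta_area = waveform_area(tk$ersp, config$ersp_test_window_ms),
        pes_median_ms = tk$pes_med
      )
    }
    if (ok) {
      rsi_rows[[length(rsi_rows) + 1L]] <- tibble::tibble(subject = f$subject,
        rsi_t1 = f$tertiles[[1]]$rsi, rsi_t2 = f$tertiles[[2]]$rsi,
        rsi_t3 = f$tertiles[[3]]$rsi)
    }
  }
  areas <- dplyr::bind_rows(rows)
  out <- list(areas = areas, anova = NULL, posthoc = NULL,
    rsi = dplyr::bind_rows(rsi_rows), log = dplyr::bind_rows(log))
  if (!nrow(areas) || length(unique(areas$subject)) < 3) return(out)

  wide <- tidyr::pivot_wider(areas, id_cols = "subject",
    names_from = "tertile", values_from = c("ern_area", "theta_area"))
  n <- nrow(wide)
  anova <- dplyr::bind_rows(
    dplyr::mutate(oneway_anova(areas$ern_area, areas$tertile),
      measure = "ern_area", .before = 1),
    dplyr::mutate(oneway_anova(areas$theta_area, areas$tertile),
      measure = "theta_area", .before = 1)
  )
  ph <- list()
  for (meas in c("ern_area", "theta_area")) {
    for (pr in list(c(3, 2), c(3, 1), c(2, 1))) {
      x <- wide[[sprintf("%s_%d", meas, pr[1])]]
      y <- wide[[sprintf("%s_%d", meas, pr[2])]]
      tt <- paired_t_test(x, y)
      ph[[length(ph) + 1L]] <- dplyr::mutate(tt, measure = meas,
        comparison = sprintf("t%d_vs_t%d", pr[1], pr[2]),
        r = round(effect_size_r(.data$t, n), 2), .before = 1)
    }
  }
  out$anova <- anova
  out$posthoc <- dplyr::bind_rows(ph)
  out$bonferroni_alpha <- bonferroni_alpha(config$bonferroni_family_alpha,
    config$bonferroni_m)
  out
}
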