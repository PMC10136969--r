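#' Classify trial outcomes
#'
#' Labels each trial from its stimulus class and response flag:
#' go+response = `hit`, go+no response = `omission`, no-go+response =
#' `false_alarm` (commission error), no-go+no response =
#' `correct_rejection`.
#'
#' @param trials A tibble with columns `stimulus` (`"go"`/`"nogo"`; the
#'   spellings `"no-go"` and `"no_go"` are normalized) and `response`
#'   (logical).
#' @return `trials` with a (re)computed `outcome` column.
#' @examples
#' classify_outcomes(tibble::tibble(stimulus = c("go", "nogo"),
#'   response = c(TRUE, TRUE)))
#' @export
classify_outcomes <- function(trials) {
  if (!all(c("stimulus", "response") %in% names(trials))) {
    abort("`trials` must have `stimulus` and `response` columns.",
      class = "gng_data_error")
  }
  stim <- gsub("[-_]", "", tolower(trials$stimulus))
  bad <- !stim %in% c("go", "nogo")
  if (any(bad)) {
    abort(sprintf("Unknown stimulus class: %s",
      paste(unique(trials$stimulus[bad]), collapse = ", ")),
      class = "gng_data_error")
  }
  trials$stimulus <- ifelse(stim == "go", "go", "nogo")
  trials$outcome <- dplyr::case_when(
    stim == "go" & trials$response ~ "hit",
    stim == "go" & !trials$response ~ "omission",
    stim == "nogo" & trials$response ~ "false_alarm",
    TRUE ~ "correct_rejection"
  )
  trials
}

#' Median and quartiles of reaction times per outcome class
#'
#' Computes the median, first and third quartiles of RT over hits
#' (correct-trial RT), over false alarms (error-trial RT), and pooled over
#' all responded trials (overall RT). Classes with no responded trials are
#' omitted from the result.
#'
#' @param trials A classified trial tibble (see [classify_outcomes()]).
#' @return A tibble with columns `measure`, `median`, `q25`, `q75`, `n`.
#' @export
rt_summaries <- function(trials) {
  trials <- ensure_classified(trials)
  resp <- dplyr::filter(trials, .data$response & !is.na(.data$rt_ms))
  one <- function(label, rts) {
    if (length(rts) == 0L) return(NULL)
    q <- unname(quantile(rts, c(0.25, 0.5, 0.75)))
    tibble::tibble(measure = label, median = q[2], q25 = q[1], q75 = q[3],
      n = length(rts))
  }
  empty <- tibble::tibble(measure = character(0), median = numeric(0),
    q25 = numeric(0), q75 = numeric(0), n = integer(0))
  dplyr::bind_rows(
    empty,
    one("overall_rt_ms", resp$rt_ms),
    one("correct_rt_ms", resp$rt_ms[resp$outcome == "hit"]),
    one("error_rt_ms", resp$rt_ms[resp$outcome == "false_alarm"])
  )
}

ensure_classified <- function(trials) {
  if (!"outcome" %in% names(trials)) classify_outcomes(trials) else trials
}

#' Current/next trial adjustment pairs for post-error or post-correct slowing
#'
#' For every trial of the requested current outcome whose immediate
#' successor exists within the same block, builds a pair carrying the
#' current RT, the next-trial RT (NA when the successor was not responded),
#' their difference (`slowing_ms = next - current`), and the successor's
#' outcome. Pairs whose successor was unresponded are retained (they count
#' for accuracy denominator bookkeeping) with undefined slowing.
#'
#' @param trials A classified trial tibble, one or more subjects.
#' @param current_outcome `"false_alarm"` for post-error pairs (PES) or
#'   `"hit"` for post-correct pairs (PCS).
#' @return A tibble with columns `subject`, `block`, `trial`, `next_trial`,
#'   `rt_ms`, `next_rt_ms`, `slowing_ms`, `next_outcome`, `next_responded`.
#' @export
post_slowing_pairs <- function(trials, current_outcome = c("false_alarm", "hit")) {
  current_outcome <- match.arg(current_outcome)
  trials <- ensure_classified(trials)
  trials <- dplyr::arrange(trials, .data$subject, .data$block, .data$trial)
  grp <- dplyr::group_by(trials, .data$subject, .data$block)
  aug <- dplyr::mutate(grp,
    next_trial = dplyr::lead(.data$trial),
    next_rt_ms = dplyr::lead(.data$rt_ms),
    next_outcome = dplyr::lead(.data$outcome),
    next_responded = dplyr::lead(.data$response)
  )
  aug <- dplyr::ungroup(aug)
  pairs <- dplyr::filter(aug,
    .data$outcome == current_outcome, .data$response, !is.na(.data$next_trial))
  dplyr::transmute(pairs,
    subject = .data$subject, block = .data$block, trial = .data$trial,
    next_trial = .data$next_trial, rt_ms = .data$rt_ms,
    next_rt_ms = .data$next_rt_ms,
    slowing_ms = .data$next_rt_ms - .data$rt_ms,
    next_outcome = .data$next_outcome,
    next_responded = .data$next_responded
  )
}

#' RT-matched post-correct slowing (or accuracy) control
#'
#' Post-correct pairs are RT-matched to post-error pairs to control for
#' regression toward the mean: in each of `n_repeats` repeats, the
#' post-error pairs are visited in random order and each one selects,
#' without replacement, the post-correct pair whose current-trial RT is
#' nearest (ties broken uniformly at random). The repeat's statistic is the
#' mean slowing (`statistic = "slowing"`) or the percentage of hit
#' successors (`statistic = "accuracy"`) over the selected post-correct
#' pairs; the final value is the mean of the repeat statistics.
#'
#' When there are fewer post-correct than post-error pairs the selection
#' falls back to sampling with replacement and flags the result.
#'
#' @param pes_pairs,pcs_pairs Pair tibbles from [post_slowing_pairs()] for a
#'   single subject. For `statistic = "slowing"` only pairs with defined
#'   slowing are used; for `"accuracy"`, pairs with responded successors.
#' @param n_repeats Number of matching repeats (default 20).
#' @param seed Integer seed; the procedure is deterministic given the seed.
#' @param statistic `"slowing"` (mean PCS, ms) or `"accuracy"` (PCA, %).
#' @return A list with `mean` (the matched control value), `repeat_values`,
#'   and `with_replacement` (logical flag).
#' @export
rt_matched_control <- function(pes_pairs, pcs_pairs, n_repeats = 20, seed = NULL,
                               statistic = c("slowing", "accuracy")) {
  statistic <- match.arg(statistic)
  if (statistic == "slowing") {
    pes <- dplyr::filter(pes_pairs, !is.na(.data$slowing_ms))
    pcs <- dplyr::filter(pcs_pairs, !is.na(.data$slowing_ms))
  } else {
    pes <- dplyr::filter(pes_pairs, .data$next_responded)
    pcs <- dplyr::filter(pcs_pairs, .data$next_responded)
  }
  if (nrow(pes) == 0L || nrow(pcs) == 0L) {
    return(list(mean = NA_real_, repeat_values = numeric(0),
      with_replacement = FALSE))
  }
  replace <- nrow(pcs) < nrow(pes)
  if (replace) {
    warn("Fewer post-correct than post-error pairs; matching with replacement.")
  }
  vals <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      sel <- match_one_repeat(pes$rt_ms, pcs$rt_ms, replace)
      if (statistic == "slowing") {
        mean(pcs$slowing_ms[sel])
      } else {
        100 * mean(pcs$next_outcome[sel] == "hit")
      }
    }, numeric(1))
  })
  list(mean = mean(vals), repeat_values = vals, with_replacement = replace)
}

#' @rdname rt_matched_control
#' @export
rt_matched_pcs <- function(pes_pairs, pcs_pairs, n_repeats = 20, seed = NULL) {
  rt_matched_control(pes_pairs, pcs_pairs, n_repeats, seed, "slowing")
}

match_one_repeat <- function(pes_rt, pcs_rt, replace) {
  order_pes <- sample.int(length(pes_rt))
  available <- rep(TRUE, length(pcs_rt))
  sel <- integer(length(pes_rt))
  for (i in order_pes) {
    pool <- if (replace) seq_along(pcs_rt) else which(available)
    d <- abs(pcs_rt[pool] - pes_rt[i])
    best <- pool[d <= min(d) + 1e-9]
    pick <- if (length(best) == 1L) best else sample(best, 1L)
    sel[i] <- pick
    if (!replace) available[pick] <- FALSE
  }
  sel
}

#' Post-event accuracy
#'
#' Percentage of responded successors that are hits among a set of
#' adjustment pairs: `100 * hits / (hits + false alarms)`. Unresponded
#' successors are excluded from the denominator. Returns `NA` when no
#' successor was responded.
#'
#' @param pairs A pair tibble from [post_slowing_pairs()].
#' @return A percentage in `[0, 100]`, or `NA`.
#' @examples
#' post_accuracy(tibble::tibble(next_outcome = c("hit", "hit", "false_alarm",
#'   "hit"), next_responded = TRUE))
#' @export
post_accuracy <- function(pairs) {
  resp <- dplyr::filter(pairs, .data$next_responded)
  if (nrow(resp) == 0L) return(NA_real_)
  100 * sum(resp$next_outcome == "hit") / nrow(resp)
}

#' Split values into tertiles by rank
#'
#' Rank-sorts the values and cuts at ranks `ceiling(n/3)` and
#' `ceiling(2n/3)`; ties keep their original order (stable sort), so tertile
#' sizes differ by at most one. Reports per-tertile medians of the split
#' variable.
#'
#' @param values Numeric vector of at least 3 finite values.
#' @return A list with `assignment` (tertile 1-3 per input element, input
#'   order), `medians` (length 3), and `sizes`.
#' @examples
#' tertile_split(1:9)$sizes
#' @export
tertile_split <- function(values) {
  if (length(values) < 3L || any(!is.finite(values))) {
    abort("Tertile split needs at least 3 finite values.", class = "gng_split_error")
  }
  n <- length(values)
  ord <- order(values)                       # stable: ties by original order
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  assignment <- integer(n)
  assignment[ord[seq_len(cut1)]] <- 1L
  assignment[ord[seq(cut1 + 1L, cut2)]] <- 2L
  assignment[ord[seq(cut2 + 1L, n)]] <- 3L
  list(
    assignment = assignment,
    medians = vapply(1:3, function(k) median(values[assignment == k]), numeric(1)),
    sizes = tabulate(assignment, 3L)
  )
}

#' Response-stimulus interval per trial
#'
#' The RSI is the time between a response and the next stimulus onset. With
#' the fixed task cadence (400 ms stimulus + 800 ms cross), it is
#' `soa_ms - rt_ms` exactly. Defined only for responded trials with a
#' successor in the same block; elsewhere `NA`.
#'
#' @param trials A trial tibble with `subject`, `block`, `trial`,
#'   `response`, `rt_ms`.
#' @param soa_ms Onset-to-onset interval (default 1200 ms).
#' @return `trials` with an added `rsi_ms` column.
#' @export
compute_rsi <- function(trials, soa_ms = 1200) {
  trials <- dplyr::arrange(trials, .data$subject, .data$block, .data$trial)
  grp <- dplyr::group_by(trials, .data$subject, .data$block)
  out <- dplyr::mutate(grp,
    has_next = !is.na(dplyr::lead(.data$trial)),
    rsi_ms = ifelse(.data$response & .data$has_next, soa_ms - .data$rt_ms, NA_real_)
  )
  dplyr::select(dplyr::ungroup(out), -"has_next")
}

#' Subject inclusion filter
#'
#' Retains subjects whose per-analysis trial/epoch counts meet the minimum
#' (at least 7 artifact-free error trials; for tertile analyses, at least 7
#' per tertile), and logs every decision.
#'
#' @param counts A tibble with a `subject` column and one or more numeric
#'   count columns (one per inclusion cell, e.g. per tertile).
#' @param min_per_cell Minimum count required in every cell (default 7).
#' @return A list with `retained` (subject ids) and `log` (the counts tibble
#'   plus a `retained` flag).
#' @examples
#' inclusion_filter(tibble::tibble(subject = 1:2, n_errors = c(6, 7)))
#' @export
inclusion_filter <- function(counts, min_per_cell = 7) {
  cells <- dplyr::select(counts, -"subject")
  ok <- apply(as.matrix(cells), 1, function(r) all(!is.na(r) & r >= min_per_cell))
  list(
    retained = counts$subject[ok],
    log = dplyr::mutate(counts, retained = ok)
  )
}

#' Per-subject behavioral summary
#'
#' Computes, for each subject: hit and false-alarm percentages, overall /
#' correct-trial / error-trial median RTs, single-trial PES and the
#' RT-matched PCS control, PEA and the matched PCA control. Measures whose
#' defining trial set is empty are `NA`.
#'
#' @param trials A classified multi-subject trial tibble.
#' @param n_repeats Matching repeats for the PCS/PCA controls (default 20).
#' @param seed Integer seed for the matching procedure.
#' @param successors Which successor trials enter the slowing averages:
#'   `"any"` (default) keeps every responded successor, `"hit"` restricts
#'   PES/PCS to pairs whose successor was a hit.
#' @return A tibble with one row per subject.
#' @export
subject_behavior_summary <- function(trials, n_repeats = 20, seed = NULL,
                                     successors = c("any", "hit")) {
  successors <- match.arg(successors)
  trials <- ensure_classified(trials)
  subjects <- sort(unique(trials$subject))
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[i]
    tr <- dplyr::filter(trials, .data$subject == s)
    go_n <- sum(tr$stimulus == "go")
    nogo_n <- sum(tr$stimulus == "nogo")
    rts <- rt_summaries(tr)
    pes_pairs <- post_slowing_pairs(tr, "false_alarm")
    pcs_pairs <- post_slowing_pairs(tr, "hit")
    if (successors == "hit") {
      hit_only <- function(p) {
        dplyr::mutate(p, slowing_ms = ifelse(.data$next_outcome == "hit",
          .data$slowing_ms, NA_real_))
      }
      pes_pairs <- hit_only(pes_pairs)
      pcs_pairs <- hit_only(pcs_pairs)
    }
    sub_seed <- if (is.null(seed)) NULL else seed + i
    mpcs <- rt_matched_control(pes_pairs, pcs_pairs, n_repeats, sub_seed, "slowing")
    mpca <- rt_matched_control(pes_pairs, pcs_pairs, n_repeats,
      if (is.null(sub_seed)) NULL else sub_seed + 1L, "accuracy")
    pick <- function(m) {
      v <- rts$median[rts$measure == m]
      if (length(v)) v else NA_real_
    }
    tibble::tibble(
      subject = s,
      hit_pct = if (go_n) 100 * sum(tr$outcome == "hit") / go_n else NA_real_,
      false_alarm_pct = if (nogo_n) 100 * sum(tr$outcome == "false_alarm") / nogo_n else NA_real_,
      overall_rt_ms = pick("overall_rt_ms"),
      correct_rt_ms = pick("correct_rt_ms"),
      error_rt_ms = pick("error_rt_ms"),
      pes_ms = if (any(!is.na(pes_pairs$slowing_ms))) {
        mean(pes_pairs$slowing_ms, na.rm = TRUE)
      } else NA_real_,
      matched_pcs_ms = mpcs$mean,
      pea_pct = post_accuracy(pes_pairs),
      matched_pca_pct = mpca$mean,
      n_error_trials = sum(tr$outcome == "false_alarm")
    )
  })
  dplyr::bind_rows(rows)
}

#' Cohort-level descriptive table of behavioral measures
#'
#' Median and quartiles across subjects of each per-subject behavioral
#' measure, mirroring the layout of a descriptive behavior table
#' (hits %, false alarms %, overall/correct/error RT, PCS, PES, PCA, PEA).
#'
#' @param summaries Output of [subject_behavior_summary()].
#' @return A tibble with columns `measure`, `median`, `q25`, `q75`, `n`.
#' @export
cohort_behavior_table <- function(summaries) {
  measures <- c(
    "hit_pct", "false_alarm_pct", "overall_rt_ms", "correct_rt_ms",
    "error_rt_ms", "matched_pcs_ms", "pes_ms", "matched_pca_pct", "pea_pct"
  )
  rows <- lapply(measures, function(m) {
    v <- summaries[[m]]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
    tibble::tibble(measure = m, median = q[2], q25 = q[1], q75 = q[3], n = length(v))
  })
  dplyr::bind_rows(rows)
}
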