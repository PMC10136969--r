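#' Simulate a full synthetic cohort
#'
#' Draws a task sequence and behavioral responses for every subject and
#' prepares per-subject EEG seeds. Recordings are synthesized lazily —
#' [subject_recording()] regenerates a subject's continuous EEG
#' deterministically on demand — so cohorts of realistic size do not hold
#' gigabytes of signal in memory.
#'
#' @param params A [synth_params()] object.
#' @param seed Integer master seed; the whole cohort is a pure function of
#'   `(params, seed)`.
#' @return A `gng_cohort`: list with `trials` (classified behavior tibble
#'   for all subjects), `params`, `seed`, and `eeg_seeds`.
#' @examples
#' coh <- simulate_cohort(synth_params(n_subjects = 2,
#'   blocks_per_subject = 1), seed = 1)
#' dplyr::count(coh$trials, outcome)
#' @export
simulate_cohort <- function(params, seed) {
  stopifnot(inherits(params, "gng_params"))
  seeds <- with_seed(seed, {
    list(
      seq_seed = sample.int(.Machine$integer.max - 1L, 1L),
      beh_seed = sample.int(.Machine$integer.max - 1L, 1L),
      eeg_seeds = sample.int(.Machine$integer.max - 1L, params$n_subjects)
    )
  })
  sequence <- simulate_task_sequence(params, seeds$seq_seed)
  trials <- simulate_behavior(sequence, params, seeds$beh_seed)
  structure(
    list(trials = trials, params = params, seed = seed,
      eeg_seeds = seeds$eeg_seeds, recordings = NULL),
    class = "gng_cohort"
  )
}

#' Continuous EEG for one subject of a cohort
#'
#' For synthetic cohorts the recording is regenerated deterministically from
#' the cohort's per-subject seed; cohorts built from files
#' ([cohort_from_data()]) return the stored recording.
#'
#' @param cohort A `gng_cohort`.
#' @param subject Subject id.
#' @return A `gng_raw` recording.
#' @export
subject_recording <- function(cohort, subject) {
  stopifnot(inherits(cohort, "gng_cohort"))
  if (!is.null(cohort$recordings)) {
    rec <- cohort$recordings[[as.character(subject)]]
    if (is.null(rec)) {
      abort(sprintf("No recording stored for subject %s.", subject),
        class = "gng_data_error")
    }
    return(rec)
  }
  idx <- match(subject, sort(unique(cohort$trials$subject)))
  if (is.na(idx)) {
    abort(sprintf("Unknown subject %s.", subject), class = "gng_data_error")
  }
  beh <- dplyr::filter(cohort$trials, .data$subject == !!subject)
  simulate_eeg(beh, cohort$params, cohort$eeg_seeds[idx])
}

#' Assemble a cohort from existing tables and recordings
#'
#' Entry point for real (non-synthetic) data: supply a classified trial
#' table (the events-table dialect written by [write_events_tsv()]) and a
#' named list of `gng_raw` recordings, one per subject.
#'
#' @param trials Classified trial tibble for all subjects.
#' @param recordings Named list (by subject id) of `gng_raw` objects.
#' @param params Optional [synth_params()] carrying design constants
#'   (`soa_ms` etc.); defaults to `synth_params()`.
#' @return A `gng_cohort`.
#' @export
cohort_from_data <- function(trials, recordings, params = synth_params()) {
  trials <- ensure_classified(trials)
  missing <- setdiff(as.character(unique(trials$subject)), names(recordings))
  if (length(missing)) {
    abort(sprintf("Recordings missing for subjects: %s",
      paste(missing, collapse = ", ")), class = "gng_data_error")
  }
  structure(
    list(trials = trials, params = params, seed = NA_integer_,
      eeg_seeds = NULL, recordings = recordings),
    class = "gng_cohort"
  )
}

#' @export
print.gng_cohort <- function(x, ...) {
  ns <- length(unique(x$trials$subject))
  cat(sprintf("<gng_cohort> %d subjects, %d trials (%s recordings)\n",
    ns, nrow(x$trials),
    if (is.null(x$recordings)) "lazily synthesized" else "stored"))
  invisible(x)
}
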