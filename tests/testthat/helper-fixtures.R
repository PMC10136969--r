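# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Small behavioral cohort (no EEG needed): 60 subjects x 4 blocks, defaults.
behavior_cohort <- function() {
  get_fixture("behavior_cohort", function() {
    simulate_cohort(synth_params(n_subjects = 60, blocks_per_subject = 4), seed = 7)
  })
}

# Small EEG cohort with a strong injected ERN, artifact-free (ICA off in the
# configs that consume it); used by preprocessing and pipeline tests.
eeg_cohort <- function() {
  get_fixture("eeg_cohort", function() {
    simulate_cohort(
      synth_params(n_subjects = 14, blocks_per_subject = 2, blink_rate_hz = 0,
        ern_amp_uv = 10),
      seed = 101
    )
  })
}

fast_config <- function(...) {
  analysis_config(run_ica = FALSE, n_perm = 500, ...)
}

# Per-subject neural features for the shared EEG cohort (expensive; cached).
eeg_features <- function() {
  get_fixture("eeg_features", function() {
    coh <- eeg_cohort()
    cfg <- fast_config()
    suppressMessages(lapply(sort(unique(coh$trials$subject)), function(s) {
      gonogoeeg:::subject_neural_features(coh, s, cfg)
    }))
  })
}

stack_feature <- function(feats, field) {
  do.call(rbind, lapply(feats, function(f) f[[field]]$value))
}

# One-subject raw recording with blinks, shared by ICA tests.
blink_recording <- function() {
  get_fixture("blink_recording", function() {
    coh <- simulate_cohort(
      synth_params(n_subjects = 1, blocks_per_subject = 2, blink_rate_hz = 0.15),
      seed = 5
    )
    subject_recording(coh, 1)
  })
}

# Kolmogorov-Smirnov distance between two samples (brute-force ecdf oracle).
ks_distance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}
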