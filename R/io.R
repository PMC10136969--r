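#' Write / read continuous EEG as plain CSV
#'
#' One column per channel, header row of 10-20 labels, one row per sample.
#' The sampling rate travels in a `# fs=<Hz>` comment on the first line.
#'
#' @param raw A `gng_raw` recording.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(raw, path) {
  stopifnot(inherits(raw, "gng_raw"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", raw$fs), con)
  df <- as.data.frame(raw$data)
  names(df) <- raw$channels
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @param events Events tibble to attach to the recording (see
#'   [write_events_tsv()]); optional.
#' @param subject Subject id to attach.
#' @export
read_eeg_csv <- function(path, events = NULL, subject = NA) {
  first <- readLines(path, n = 1L)
  fs <- if (grepl("^# fs=", first)) as.numeric(sub("^# fs=", "", first)) else {
    abort("Missing `# fs=` header line.", class = "gng_data_error")
  }
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  ev <- if (is.null(events)) {
    tibble::tibble(sample = integer(0), block = integer(0), trial = integer(0),
      stimulus = character(0), outcome = character(0), rt_ms = numeric(0),
      slowing_ms = numeric(0), next_outcome = character(0),
      next_responded = logical(0))
  } else {
    events
  }
  new_gng_raw(as.matrix(df), names(df), fs, ev, subject = subject)
}

#' Write / read the per-trial events table
#'
#' Tab-separated, one row per trial, with columns `onset_ms`, `block`,
#' `trial_index`, `stimulus` (`go`/`no-go`), `response` (0/1), `rt_ms`,
#' `outcome` (and `subject` when more than one is present).
#'
#' @param trials A classified trial tibble.
#' @param path Output file.
#' @return `path` invisibly; `read_events_tsv()` returns the trials tibble.
#' @export
write_events_tsv <- function(trials, path) {
  trials <- ensure_classified(trials)
  out <- data.frame(
    subject = trials$subject,
    onset_ms = trials$onset_ms,
    block = trials$block,
    trial_index = trials$trial,
    stimulus = ifelse(trials$stimulus == "go", "go", "no-go"),
    response = as.integer(trials$response),
    rt_ms = trials$rt_ms,
    outcome = trials$outcome
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  tibble::tibble(
    subject = df$subject,
    block = df$block,
    trial = df$trial_index,
    stimulus = ifelse(df$stimulus == "go", "go", "nogo"),
    onset_ms = df$onset_ms,
    response = df$response == 1,
    rt_ms = ifelse(df$response == 1, df$rt_ms, NA_real_),
    outcome = df$outcome
  )
}

#' Export response-locked epochs as flat CSV plus a JSON sidecar
#'
#' The CSV holds one row per (epoch, channel, sample) value; the sidecar
#' records the time axis, channel labels, rejection mask and per-epoch trial
#' linkage, so the array can be reassembled exactly.
#'
#' @param epochs A `gng_epochs` object.
#' @param path_csv,path_json Output files.
#' @return `path_csv`, invisibly.
#' @export
export_epochs <- function(epochs, path_csv, path_json) {
  stopifnot(inherits(epochs, "gng_epochs"))
  d <- epochs$data
  long <- data.frame(
    epoch = rep(seq_len(dim(d)[1]), times = dim(d)[2] * dim(d)[3]),
    channel = rep(rep(epochs$channels, each = dim(d)[1]), times = dim(d)[3]),
    time_ms = rep(epochs$time_ms, each = dim(d)[1] * dim(d)[2]),
    value = as.vector(d)
  )
  utils::write.csv(long, path_csv, row.names = FALSE)
  side <- list(
    time_ms = epochs$time_ms, channels = epochs$channels, fs = epochs$fs,
    rejected = epochs$rejected, info = epochs$info, dropped = epochs$dropped
  )
  jsonlite::write_json(side, path_json, auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(path_csv)
}
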