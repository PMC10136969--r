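#' Generate a go/no-go trial sequence
#'
#' Draws independent per-trial stimulus classes with `P(go) = p_go` and lays
#' trials out in blocks of `trials_per_block` with a fixed onset-to-onset
#' spacing of `soa_ms`. Blocks are separated by a noise-only gap
#' (`params$block_gap_ms`), and the session starts after one such gap so
#' response-locked epochs never run off the front of the recording.
#'
#' @param params A [synth_params()] object.
#' @param seed Integer seed; the sequence is a pure function of
#'   `(params, seed)`.
#' @param n_subjects Optionally override `params$n_subjects`.
#' @return A tibble with columns `subject`, `block`, `trial` (within-block
#'   index), `stimulus` (`"go"`/`"nogo"`), `onset_ms` (session time).
#' @examples
#' seqs <- simulate_task_sequence(synth_params(n_subjects = 1,
#'   blocks_per_subject = 1), seed = 1)
#' table(seqs$stimulus)
#' @export
simulate_task_sequence <- function(params, seed, n_subjects = NULL) {
  stopifnot(inherits(params, "gng_params"))
  n_subj <- if (is.null(n_subjects)) params$n_subjects else as.integer(n_subjects)
  with_seed(seed, {
    per_subject <- lapply(seq_len(n_subj), function(s) {
      n_blocks <- if (length(params$blocks_per_subject) == 1L) {
        params$blocks_per_subject
      } else {
        sample(params$blocks_per_subject, 1L)
      }
      ntr <- params$trials_per_block
      block <- rep(seq_len(n_blocks), each = ntr)
      trial <- rep(seq_len(ntr), times = n_blocks)
      block_start <- params$block_gap_ms +
        (block - 1L) * (ntr * params$soa_ms + params$block_gap_ms)
      onset <- block_start + (trial - 1L) * params$soa_ms
      stim <- ifelse(runif(n_blocks * ntr) < params$p_go, "go", "nogo")
      tibble::tibble(
        subject = s, block = block, trial = trial,
        stimulus = stim, onset_ms = onset
      )
    })
    dplyr::bind_rows(per_subject)
  })
}

#' Analytic consecutive-pair probabilities of the task design
#'
#' Under independent per-trial stimulus draws with `P(go) = p_go`, the four
#' consecutive-trial type probabilities are the products of the marginals.
#' Useful for auditing the scarcity of double no-go (hence double-error)
#' trials the design produces.
#'
#' @param p_go Probability of a go stimulus.
#' @return A tibble with columns `pair` and `probability` for the four
#'   ordered pairs (nogo-nogo, nogo-go, go-nogo, go-go).
#' @examples
#' consecutive_pair_probabilities(0.7)
#' @export
consecutive_pair_probabilities <- function(p_go = 0.7) {
  assert_probability(p_go, "p_go")
  q <- 1 - p_go
  tibble::tibble(
    pair = c("nogo-nogo", "nogo-go", "go-nogo", "go-go"),
    probability = c(q * q, q * p_go, p_go * q, p_go * p_go)
  )
}
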