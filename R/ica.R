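#' Remove artifact components from a continuous recording
#'
#' Linearly decomposes the channels into at most 14 independent components
#' (FastICA: whitening by eigendecomposition, then a symmetric fixed-point
#' iteration with the tanh contrast). Components are flagged for removal
#' when their time course correlates with the supplied blink/artifact
#' reference trace (|r| >= `r_threshold`), or — when no reference is
#' available — when both their frontal loading share (AF3/AF4) and their
#' kurtosis exceed the configured thresholds. Flagged components are zeroed
#' and the signal rebuilt from the rest; with nothing flagged the
#' reconstruction equals the input to numerical precision.
#'
#' @param raw A (typically bandpass-filtered) `gng_raw` recording.
#' @param reference Optional artifact reference trace, one value per sample
#'   (synthetic recordings carry their ground-truth blink trace in
#'   `$blink_ref`).
#' @param r_threshold Absolute correlation above which a component is
#'   removed (default 0.7).
#' @param frontal_share_threshold,kurtosis_threshold Automatic selection
#'   thresholds used when no reference is given.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param seed Seed for the (deterministic) random orthonormal start.
#' @return A list with `raw` (cleaned recording) and `report` (one row per
#'   component: reference correlation, kurtosis, frontal share, removal
#'   flag).
#' @export
remove_artifact_components <- function(raw, reference = NULL, r_threshold = 0.7,
                                       frontal_share_threshold = 0.5,
                                       kurtosis_threshold = 8,
                                       max_iter = 200, tol = 1e-6, seed = 1) {
  stopifnot(inherits(raw, "gng_raw"))
  X <- raw$data
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)

  eg <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  keep_ev <- eg$values > max(eg$values) * 1e-10
  if (!any(keep_ev)) {
    abort("Degenerate covariance: decomposition failed.", class = "gng_decomposition_error")
  }
  E <- eg$vectors[, keep_ev, drop = FALSE]
  lam <- eg$values[keep_ev]
  K <- E %*% diag(1 / sqrt(lam), length(lam))       # channels x k whitener
  Z <- Xc %*% K                                     # n x k, white

  k <- ncol(Z)
  W <- with_seed(seed, {
    w0 <- matrix(rnorm(k * k), k, k)
    sv <- svd(w0)
    sv$u %*% t(sv$v)
  })
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)                                # n x k sources
    G <- tanh(WX)
    gp <- colMeans(1 - G^2)
    W1 <- crossprod(G, Z) / n - diag(gp, k) %*% W
    sv <- svd(W1)
    W1 <- sv$u %*% t(sv$v)                          # symmetric decorrelation
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (!all(is.finite(W))) {
      abort(sprintf("ICA diverged at iteration %d.", it),
        class = "gng_decomposition_error")
    }
    if (delta < tol) break
  }

  S <- Z %*% t(W)                                   # n x k unit-variance sources
  # mixing matrix: Xc = S %*% A with A = W %*% diag(sqrt(lam)) %*% t(E)
  A <- W %*% (t(E) * sqrt(lam))

  fr_idx <- match(c("AF3", "AF4"), raw$channels)
  frontal_share <- if (anyNA(fr_idx)) rep(NA_real_, k) else {
    apply(A, 1, function(a) sum(abs(a[fr_idx])) / sum(abs(a)))
  }
  kurt <- apply(S, 2, sample_kurtosis)
  r_ref <- if (!is.null(reference) && sd(reference) > 0) {
    as.numeric(abs(cor(S, reference)))
  } else {
    rep(NA_real_, k)
  }

  removed <- if (any(!is.na(r_ref))) {
    !is.na(r_ref) & r_ref >= r_threshold
  } else {
    !is.na(frontal_share) & frontal_share >= frontal_share_threshold &
      kurt >= kurtosis_threshold
  }

  if (any(removed)) {
    raw$data <- S[, !removed, drop = FALSE] %*% A[!removed, , drop = FALSE] +
      rep(mu, each = n)
  } else {
    # exact identity when the whitening kept full rank
    raw$data <- S %*% A + rep(mu, each = n)
  }

  list(
    raw = raw,
    report = tibble::tibble(
      component = seq_len(k),
      cor_reference = r_ref,
      kurtosis = kurt,
      frontal_share = frontal_share,
      removed = removed
    )
  )
}
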