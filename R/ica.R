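#' Independent component analysis of a recording
#'
#' Whitens the channel data and maximizes non-Gaussianity of the projected
#' sources (fixed-point iteration with the logcosh contrast and symmetric
#' decorrelation). Returns as many components as channels; the
#' decomposition is deterministic given the seed, and
#' `mixing %*% sources` reconstructs the input (after removing channel
#' means) to numerical precision.
#'
#' @param recording An [eeg_recording()] with at least `14 * 100` samples.
#' @param rng_seed Integer seed for the random orthogonal initialisation.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return An object of class `ica_decomposition` with fields `mixing`
#'   (channel x component), `sources` (component x sample),
#'   `channel_means`, `channels`, `fs_hz`.
#' @export
fit_ica <- function(recording, rng_seed = 1, max_iter = 200, tol = 1e-6) {
  X <- recording$data
  p <- nrow(X)
  n <- ncol(X)
  if (n < p * 100) {
    stop("need at least ", p * 100, " samples for a stable decomposition; ",
         "got ", n, call. = FALSE)
  }
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < max(eg$values) * 1e-10) {
    stop("degenerate input: channel covariance is rank-deficient ",
         "(duplicated or constant channels?)", call. = FALSE)
  }
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)   # whitening matrix
  Z <- K %*% Xc                                      # whitened data

  W <- with_local_seed(rng_seed, {
    M <- matrix(stats::rnorm(p * p), p, p)
    qr.Q(qr(M))
  })
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / n - diag(rowMeans(Gp)) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  S <- W %*% Z
  # Fix sign convention: skew each source positive, then order by kurtosis.
  sgn <- ifelse(rowMeans(S^3) >= 0, 1, -1)
  S <- S * sgn
  W <- W * sgn
  A <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(W)  # unmixing inverse
  ord <- order(apply(S, 1, pearson_kurtosis), decreasing = TRUE)
  structure(
    list(mixing = A[, ord, drop = FALSE],
         sources = S[ord, , drop = FALSE],
         channel_means = mu,
         channels = recording$channels,
         fs_hz = recording$fs_hz,
         n_iter = it),
    class = "ica_decomposition"
  )
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components x %d samples (%d iterations)\n",
              nrow(x$sources), ncol(x$sources), x$n_iter))
  invisible(x)
}

#' Flag artifact components of an ICA decomposition
#'
#' A component is flagged as non-neural if any of three rules fires:
#' \describe{
#'   \item{spikiness}{source kurtosis above `kurtosis_max` (electrode pops
#'     and blinks are impulsive);}
#'   \item{blink topography}{more than `low_freq_fraction` of source power
#'     below 4 Hz \emph{and} squared mixing weights concentrated on the
#'     frontal channels AF3/AF4/F7/F8;}
#'   \item{mains line}{more than `line_fraction` of source power within
#'     50 +/- 1 Hz.}
#' }
#'
#' @param decomp An `ica_decomposition`.
#' @param kurtosis_max Spikiness threshold. Default 5.
#' @param low_freq_fraction Sub-4 Hz power fraction for the blink rule.
#'   Default 0.6.
#' @param frontal_fraction Fraction of squared mixing weight that must lie
#'   on frontal channels for the blink rule. Default 0.5.
#' @param line_fraction 50 Hz power fraction for the mains rule. Default 0.5.
#' @return Integer vector of flagged component indices (possibly empty),
#'   with a `rules` attribute naming the rule(s) that fired per component.
#' @export
flag_artifact_components <- function(decomp, kurtosis_max = 5,
                                     low_freq_fraction = 0.6,
                                     frontal_fraction = 0.5,
                                     line_fraction = 0.5) {
  p <- nrow(decomp$sources)
  fs <- decomp$fs_hz
  fr_idx <- match(frontal_channels(), decomp$channels$channel)
  flags <- character(p)
  for (k in seq_len(p)) {
    s <- decomp$sources[k, ]
    spec <- compute_spectrum(s, fs)
    tot <- sum(spec$power)
    fired <- character(0)
    kur <- pearson_kurtosis(s)
    if (is.finite(kur) && kur > kurtosis_max) fired <- c(fired, "spiky")
    if (tot > 0) {
      low <- sum(spec$power[spec$freqs_hz < 4]) / tot
      w2 <- decomp$mixing[, k]^2
      frontal_share <- sum(w2[fr_idx]) / sum(w2)
      if (low > low_freq_fraction && frontal_share > frontal_fraction) {
        fired <- c(fired, "blink")
      }
      line <- sum(spec$power[abs(spec$freqs_hz - 50) <= 1]) / tot
      if (line > line_fraction) fired <- c(fired, "line")
    }
    flags[k] <- paste(fired, collapse = "+")
  }
  idx <- which(nzchar(flags))
  attr(idx, "rules") <- flags[idx]
  idx
}

#' Reconstruct a recording with components removed
#'
#' Zeroes the flagged source rows and back-projects; the retained subspace
#' is untouched, so with nothing flagged the input is recovered exactly
#' (up to the channel means, which are restored).
#'
#' @param decomp An `ica_decomposition`.
#' @param flagged Integer indices of components to remove (may be empty).
#' @param subject_id,condition Metadata for the reconstructed recording;
#'   defaults carried through if supplied.
#' @return An [eeg_recording()].
#' @export
remove_components <- function(decomp, flagged, subject_id = "reconstructed",
                              condition = "I") {
  p <- nrow(decomp$sources)
  flagged <- as.integer(flagged)
  if (length(flagged) > 0 && (min(flagged) < 1 || max(flagged) > p)) {
    stop("flagged component index out of range 1..", p, call. = FALSE)
  }
  S <- decomp$sources
  if (length(flagged) > 0) S[flagged, ] <- 0
  X <- decomp$mixing %*% S + decomp$channel_means
  eeg_recording(X, subject_id, condition, decomp$fs_hz)
}

#' Full preprocessing chain for one recording
#'
#' Baseline removal (zero-phase high-pass), ICA artifact rejection, then
#' band-limiting to the analysis range; optionally an LMS adaptive
#' canceller against a noise reference before band-limiting.
#'
#' @param recording An [eeg_recording()].
#' @param baseline_cutoff_hz High-pass edge. Default 0.5.
#' @param ica Run ICA artifact rejection? Default TRUE (skipped
#'   automatically on recordings too short for a stable fit).
#' @param rng_seed Seed for the ICA initialisation.
#' @param adaptive_reference Optional noise reference for
#'   [adaptive_denoise()]; `NULL` (default) skips the stage.
#' @param step_size LMS step when the adaptive stage runs.
#' @param bandlimit Band-limit to 4-45 Hz at the end? Default TRUE.
#' @param ... Passed to [flag_artifact_components()].
#' @return The preprocessed recording; attribute `"flagged_components"`
#'   records which ICA components were removed.
#' @export
preprocess_recording <- function(recording, baseline_cutoff_hz = 0.5,
                                 ica = TRUE, rng_seed = 1,
                                 adaptive_reference = NULL,
                                 step_size = 0.05, bandlimit = TRUE, ...) {
  out <- remove_baseline(recording, cutoff_hz = baseline_cutoff_hz)
  flagged <- integer(0)
  if (ica && n_samples(out) >= nrow(out$data) * 100) {
    decomp <- fit_ica(out, rng_seed = rng_seed)
    flagged <- flag_artifact_components(decomp, ...)
    if (length(flagged) > 0) {
      out <- remove_components(decomp, flagged,
                               subject_id = recording$subject_id,
                               condition = recording$condition)
    }
  }
  if (!is.null(adaptive_reference)) {
    out <- adaptive_denoise(out, adaptive_reference, step_size = step_size)
  }
  if (bandlimit) out <- bandlimit_recording(out)
  out$subject_id <- recording$subject_id
  out$condition <- recording$condition
  attr(out, "flagged_components") <- flagged
  out
}
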