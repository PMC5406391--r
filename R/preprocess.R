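#' Design a linear-phase FIR filter
#'
#' Windowed-sinc (Hamming) design via [signal::fir1]. The filter is the
#' classic tapped-delay line `y[n] = sum_i b_i x[n - i]`; coefficients are
#' symmetric, so a single pass is linear-phase and the forward/backward
#' application in [filter_forward_backward()] is zero-phase.
#'
#' @param kind `"low"`, `"high"` or `"pass"` (band-pass).
#' @param cutoff_hz Cutoff edge(s) in Hz (two edges for `"pass"`); all in
#'   `(0, fs_hz / 2)`.
#' @param order Filter order N (number of taps minus one), >= 2. For
#'   `"high"` the order must be even (type-I linear phase); odd orders are
#'   bumped up by one.
#' @param fs_hz Sampling rate.
#' @return An object of class `fir_filter` with fields `coefficients`,
#'   `order`, `kind`, `cutoff_hz`, `fs_hz`.
#' @examples
#' h <- design_fir("low", 45, 128, fs_hz = 128)
#' @export
design_fir <- function(kind = c("low", "high", "pass"), cutoff_hz, order,
                       fs_hz) {
  kind <- match.arg(kind)
  if (order < 2) stop("order must be >= 2", call. = FALSE)
  nyq <- fs_hz / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq)) {
    stop("invalid cutoff: must lie strictly inside (0, ", nyq, ") Hz",
         call. = FALSE)
  }
  if (kind == "pass" && length(cutoff_hz) != 2) {
    stop("band-pass design needs two cutoff edges", call. = FALSE)
  }
  if (kind != "pass" && length(cutoff_hz) != 1) {
    stop(kind, "-pass design needs a single cutoff edge", call. = FALSE)
  }
  if (kind == "high" && order %% 2 == 1) order <- order + 1
  if (kind == "high") {
    # Spectral inversion of the complementary low-pass: the low-pass is
    # normalized to unit DC gain, so the high-pass nulls DC exactly
    # (sum of coefficients == 0) — essential for baseline removal.
    lp <- signal::fir1(order, cutoff_hz / nyq, type = "low")
    b <- -lp / sum(lp)
    mid <- order / 2 + 1
    b[mid] <- b[mid] + 1
  } else {
    b <- signal::fir1(order, sort(cutoff_hz) / nyq, type = kind)
  }
  structure(
    list(coefficients = as.numeric(b), order = as.integer(order),
         kind = kind, cutoff_hz = cutoff_hz, fs_hz = fs_hz),
    class = "fir_filter"
  )
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("<fir_filter> %s-pass, order %d, cutoff %s Hz @ fs %g Hz\n",
              x$kind, x$order, paste(x$cutoff_hz, collapse = "-"), x$fs_hz))
  invisible(x)
}

#' Magnitude response of an FIR filter
#'
#' Evaluates |H(f)| by direct summation of the transfer function at the
#' requested frequencies.
#'
#' @param filter A `fir_filter`.
#' @param freq_hz Frequencies at which to evaluate.
#' @return Numeric vector of magnitudes.
#' @export
fir_response <- function(filter, freq_hz) {
  b <- filter$coefficients
  vapply(freq_hz, function(f) {
    w <- 2 * pi * f / filter$fs_hz
    Mod(sum(b * exp(-1i * w * (seq_along(b) - 1))))
  }, 0)
}

# Causal single-pass FIR via FFT convolution (keeps first length(x) samples).
fir_pass <- function(b, x) {
  n <- length(x)
  m <- length(b)
  nf <- stats::nextn(n + m - 1, 2)
  y <- Re(stats::fft(stats::fft(c(b, numeric(nf - m))) *
                       stats::fft(c(x, numeric(nf - n))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Zero-phase forward/backward filtering
#'
#' Applies the filter forward, then backward, so phase distortions cancel
#' and the effective magnitude response is the square of the single-pass
#' response. Edge transients are mitigated by odd-reflection padding of
#' length `3 * (order + 1)` at both ends.
#'
#' @param filter A `fir_filter` from [design_fir()].
#' @param signal Numeric vector, longer than `3 * (order + 1)`.
#' @return Filtered vector, same length as the input.
#' @export
filter_forward_backward <- function(filter, signal) {
  b <- filter$coefficients
  pad <- 3L * (filter$order + 1L)
  n <- length(signal)
  if (n <= pad) {
    stop("signal too short for reflection padding: need > ", pad,
         " samples, got ", n, call. = FALSE)
  }
  # Odd reflection about the end points removes step discontinuities at
  # the pad joins even for signals with DC offset or drift.
  front <- 2 * signal[1] - signal[(pad + 1):2]
  back <- 2 * signal[n] - signal[(n - 1):(n - pad)]
  xp <- c(front, signal, back)
  y <- fir_pass(b, xp)
  y <- rev(fir_pass(b, rev(y)))
  y[pad + seq_len(n)]
}

#' Remove baseline drift from a recording
#'
#' High-pass filters every channel forward/backward at a drift cutoff
#' (default 0.5 Hz, the conventional EEG choice), leaving each channel with
#' essentially zero mean and no slow drift while preserving the 4-45 Hz
#' rhythms untouched.
#'
#' @param recording An [eeg_recording()].
#' @param cutoff_hz High-pass edge in Hz. Default 0.5.
#' @param order FIR order; default 512 at 128 Hz. For short recordings the
#'   order is reduced automatically so the padding fits (never below 16).
#' @return The baseline-corrected recording.
#' @export
remove_baseline <- function(recording, cutoff_hz = 0.5, order = 512) {
  n <- n_samples(recording)
  max_order <- floor(n / 3) - 2
  if (max_order < 16) {
    stop("recording too short for baseline removal (", n, " samples)",
         call. = FALSE)
  }
  order <- min(order, max_order)
  hp <- design_fir("high", cutoff_hz, order, recording$fs_hz)
  out <- recording
  for (ci in seq_len(nrow(out$data))) {
    y <- filter_forward_backward(hp, recording$data[ci, ])
    # The passband itself carries a small finite-sample mean; remove it so
    # each channel is exactly centred.
    out$data[ci, ] <- y - mean(y)
  }
  out
}

#' Band-limit a recording to the analysis range
#'
#' Zero-phase band-pass (default 4-45 Hz) applied after artifact removal,
#' confining every channel to the union of the canonical bands.
#'
#' @param recording An [eeg_recording()].
#' @param lo_hz,hi_hz Band edges in Hz.
#' @param order FIR order (reduced automatically on short recordings).
#' @return The band-limited recording.
#' @export
bandlimit_recording <- function(recording, lo_hz = 4, hi_hz = 45,
                                order = 256) {
  n <- n_samples(recording)
  max_order <- floor(n / 3) - 2
  if (max_order < 16) {
    stop("recording too short for band-limiting (", n, " samples)",
         call. = FALSE)
  }
  order <- min(order, max_order)
  bp <- design_fir("pass", c(lo_hz, hi_hz), order, recording$fs_hz)
  out <- recording
  for (ci in seq_len(nrow(out$data))) {
    out$data[ci, ] <- filter_forward_backward(bp, recording$data[ci, ])
  }
  out
}

#' Least-mean-squares adaptive noise canceller
#'
#' Optional stage: per channel, an L-tap LMS filter adapts to the provided
#' noise reference (e.g. a mains-line track) and subtracts its best
#' prediction from the channel. With step size 0 or an all-zero reference
#' the recording is returned unchanged.
#'
#' @param recording An [eeg_recording()].
#' @param reference Numeric vector, same length as the recording.
#' @param step_size LMS step `mu` in `(0, 1)` (normalized by reference
#'   power); `0` disables adaptation.
#' @param n_taps Number of reference taps. Default 8.
#' @return The denoised recording.
#' @export
adaptive_denoise <- function(recording, reference, step_size = 0.05,
                             n_taps = 8) {
  n <- n_samples(recording)
  if (length(reference) != n) {
    stop("reference length (", length(reference),
         ") must equal the sample count (", n, ")", call. = FALSE)
  }
  if (step_size < 0 || step_size >= 1) {
    stop("step_size must lie in [0, 1)", call. = FALSE)
  }
  if (step_size == 0 || all(reference == 0)) return(recording)
  ref_power <- mean(reference^2)
  out <- recording
  for (ci in seq_len(nrow(out$data))) {
    x <- recording$data[ci, ]
    w <- numeric(n_taps)
    e <- numeric(n)
    for (t in seq_len(n)) {
      idx <- t - seq_len(n_taps) + 1L
      r <- ifelse(idx >= 1, reference[pmax(idx, 1L)], 0)
      r[idx < 1] <- 0
      yhat <- sum(w * r)
      e[t] <- x[t] - yhat
      w <- w + (step_size / (n_taps * ref_power)) * e[t] * r
    }
    out$data[ci, ] <- e
  }
  out
}
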