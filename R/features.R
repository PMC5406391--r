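#' One-sided power spectrum of a signal
#'
#' Plain full-length (rectangular-window) DFT, returned as squared
#' magnitudes `|X_k|^2` on the one-sided frequency grid. Under this
#' convention Parseval's identity reads
#' `sum_k w_k |X_k|^2 = N * sum_n x[n]^2`, with weight `w_k = 1` for the
#' DC and (even-length) Nyquist bins and `w_k = 2` otherwise.
#'
#' @param signal Numeric vector of length >= 2.
#' @param fs_hz Sampling rate.
#' @return An object of class `eeg_spectrum`: a list with `freqs_hz`,
#'   `power`, `n` (transform length) and `fs_hz`.
#' @examples
#' sp <- compute_spectrum(sin(2 * pi * 8 * (0:1023) / 128), 128)
#' sp$freqs_hz[which.max(sp$power)]
#' @export
compute_spectrum <- function(signal, fs_hz) {
  n <- length(signal)
  if (n < 2) stop("signal must have at least 2 samples", call. = FALSE)
  if (!all(is.finite(signal))) stop("signal contains non-finite values",
                                    call. = FALSE)
  X <- stats::fft(signal)
  half <- floor(n / 2)
  idx <- 1:(half + 1)              # bins 0..floor(n/2)
  structure(
    list(freqs_hz = (idx - 1) * fs_hz / n,
         power = Mod(X[idx])^2,
         n = n,
         fs_hz = fs_hz),
    class = "eeg_spectrum"
  )
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> %d one-sided bins, df = %.4g Hz, fs = %g Hz\n",
              length(x$power), x$fs_hz / x$n, x$fs_hz))
  invisible(x)
}

# Parseval weights for the one-sided grid of a spectrum.
parseval_weights <- function(spectrum) {
  w <- rep(2, length(spectrum$power))
  w[1] <- 1
  if (spectrum$n %% 2 == 0) w[length(w)] <- 1   # Nyquist bin present
  w
}

#' Spectral power in a frequency band
#'
#' Sum of `|X_k|^2` over the one-sided bins with
#' `lo_hz <= f_k <= hi_hz` (both edges inclusive) — the per-channel
#' feature the whole analysis is built on. Additive over disjoint bands.
#'
#' @param spectrum An `eeg_spectrum` from [compute_spectrum()].
#' @param band One-row band tibble or a band name.
#' @return Non-negative scalar.
#' @export
band_power <- function(spectrum, band) {
  if (is.character(band)) band <- band_definition(band)
  nyq <- spectrum$fs_hz / 2
  if (band$lo_hz < 0 || band$hi_hz > nyq) {
    stop("band [", band$lo_hz, ", ", band$hi_hz,
         "] Hz outside the spectrum's range [0, ", nyq, "]", call. = FALSE)
  }
  sel <- spectrum$freqs_hz >= band$lo_hz & spectrum$freqs_hz <= band$hi_hz
  sum(spectrum$power[sel])
}

#' Build the spectral-power feature matrix
#'
#' One row per recording, one column per (channel, band) pair: channels in
#' montage order, bands theta through gamma, columns named
#' `<channel>_<band>`. With the default cohort (20 subjects x 2
#' conditions, 14 channels x 4 bands) the result is 40 rows x 56 feature
#' columns.
#'
#' @param recordings List of [eeg_recording()] objects sharing sampling
#'   rate and montage, with both conditions present.
#' @param bands Band definition tibble; default [band_definitions()].
#' @return A tibble with columns `subject`, `condition`, then the feature
#'   columns; attribute `"col_meta"` holds the (channel, band) layout.
#' @export
build_feature_matrix <- function(recordings, bands = band_definitions()) {
  if (length(recordings) == 0) stop("no recordings supplied", call. = FALSE)
  fs <- unique(vapply(recordings, function(r) r$fs_hz, 0))
  if (length(fs) != 1) stop("recordings disagree on sampling rate: ",
                            paste(fs, collapse = ", "), call. = FALSE)
  monts <- unique(vapply(recordings,
                         function(r) paste(r$channels$channel, collapse = ","),
                         ""))
  if (length(monts) != 1) stop("recordings disagree on montage", call. = FALSE)
  conds <- vapply(recordings, function(r) r$condition, "")
  if (!all(c("I", "II") %in% conds)) {
    stop("need at least one recording per condition", call. = FALSE)
  }
  channels <- recordings[[1]]$channels$channel
  col_meta <- tidyr::expand_grid(channel = channels, band = bands$band)
  col_names <- paste(col_meta$channel, col_meta$band, sep = "_")

  rows <- purrr::map(recordings, function(rec) {
    vals <- numeric(nrow(col_meta))
    i <- 0L
    for (ch in seq_along(channels)) {
      spec <- compute_spectrum(rec$data[ch, ], rec$fs_hz)
      for (bi in seq_len(nrow(bands))) {
        i <- i + 1L
        vals[i] <- band_power(spec, bands[bi, ])
      }
    }
    vals
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- col_names
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject = vapply(recordings, function(r) r$subject_id, ""),
      condition = conds
    ),
    tibble::as_tibble(mat)
  )
  attr(out, "col_meta") <- col_meta
  out
}

#' Names of the feature columns of a feature matrix
#' @param features A tibble from [build_feature_matrix()].
#' @return Character vector of `<channel>_<band>` column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("subject", "condition"))
}

#' Pivot a feature matrix to long (tidy) form
#'
#' @param features A tibble from [build_feature_matrix()].
#' @return A tibble with columns `subject`, `condition`, `channel`, `band`,
#'   `power`.
#' @export
features_long <- function(features) {
  features |>
    tidyr::pivot_longer(dplyr::all_of(feature_columns(features)),
                        names_to = "feature", values_to = "power") |>
    tidyr::separate_wider_delim("feature", "_",
                                names = c("channel", "band"))
}
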