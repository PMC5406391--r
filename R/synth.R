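#' Construct an EEG recording object
#'
#' One subject-by-condition trial: a channel-by-sample matrix at a fixed
#' sampling rate over the 14-channel montage.
#'
#' @param data Numeric matrix, channels in rows (montage order), samples in
#'   columns; all values finite.
#' @param subject_id Subject identifier (coerced to character).
#' @param condition `"I"` (Hook / rondo) or `"II"` (Mozart / bipartite).
#' @param fs_hz Sampling rate in Hz.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, subject_id, condition, fs_hz) {
  mont <- montage_channels()
  condition <- as.character(condition)
  if (!condition %in% c("I", "II")) {
    stop("condition must be 'I' or 'II', got '", condition, "'",
         call. = FALSE)
  }
  data <- as.matrix(data)
  if (nrow(data) != nrow(mont)) {
    stop("data must have ", nrow(mont), " channel rows, got ", nrow(data),
         call. = FALSE)
  }
  if (!all(is.finite(data))) stop("data contains non-finite values",
                                  call. = FALSE)
  rownames(data) <- mont$channel
  structure(
    list(
      subject_id = as.character(subject_id),
      condition = condition,
      fs_hz = fs_hz,
      data = data,
      channels = mont
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s, condition %s: %d channels x %d samples @ %g Hz (%.4g s)\n",
    x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs_hz,
    ncol(x$data) / x$fs_hz))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Band-limited Gaussian oscillation
#'
#' Generates unit-variance Gaussian noise whose power spectrum is confined
#' to a frequency band: white noise is passed through an ideal band-pass
#' filter (frequency-domain mask, cosine-tapered inside the band so no
#' energy leaks past the edges) and rescaled to unit variance. This gives a
#' realistic broadband-within-band spectrum rather than a single spectral
#' line.
#'
#' @param band One-row band tibble (see [band_definition()]) or a band name.
#' @param n_samples Signal length (> 0).
#' @param fs_hz Sampling rate; both band edges must lie below `fs_hz / 2`.
#' @param rng_seed Integer seed; the result is deterministic given the seed.
#' @return Numeric vector of length `n_samples` with variance 1.
#' @examples
#' x <- generate_band_oscillation("alpha", 1024, 128, rng_seed = 1)
#' var(x)
#' @export
generate_band_oscillation <- function(band, n_samples, fs_hz, rng_seed) {
  if (is.character(band)) band <- band_definition(band)
  if (n_samples <= 0) stop("n_samples must be > 0 (empty signal)",
                           call. = FALSE)
  if (band$hi_hz >= fs_hz / 2 || band$lo_hz >= fs_hz / 2) {
    stop("invalid band: edge at or above Nyquist (", fs_hz / 2, " Hz)",
         call. = FALSE)
  }
  white <- with_local_seed(rng_seed, stats::rnorm(n_samples))
  y <- band_limit(white, fs_hz, band$lo_hz, band$hi_hz)
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) {
    stop("band [", band$lo_hz, ", ", band$hi_hz,
         "] Hz holds no Fourier bin at n = ", n_samples,
         "; use a longer signal", call. = FALSE)
  }
  y / s
}

# Ideal band-pass by frequency-domain masking; taper is folded inside the
# band so the output spectrum is exactly zero outside [lo, hi].
band_limit <- function(x, fs_hz, lo_hz, hi_hz) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs_hz / n   # |frequency| of each DFT bin
  width <- hi_hz - lo_hz
  taper <- min(0.5, width / 4)
  mask <- numeric(n)
  core <- f >= lo_hz + taper & f <= hi_hz - taper
  mask[core] <- 1
  rise <- f >= lo_hz & f < lo_hz + taper
  mask[rise] <- 0.5 - 0.5 * cos(pi * (f[rise] - lo_hz) / taper)
  fall <- f > hi_hz - taper & f <= hi_hz
  mask[fall] <- 0.5 - 0.5 * cos(pi * (hi_hz - f[fall]) / taper)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

# 1/f background: white noise spectrally shaped to amplitude ~ f^(-1/2),
# rescaled to the requested standard deviation.
pink_noise <- function(n, fs_hz, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  white <- stats::rnorm(n)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs_hz / n
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  y <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
  y * sd_target / stats::sd(y)
}

# Hann-windowed blink bump of given duration, unit peak.
blink_bump <- function(width_samples) {
  t <- seq_len(width_samples)
  0.5 - 0.5 * cos(2 * pi * (t - 1) / (width_samples - 1))
}

#' Generate one synthetic recording
#'
#' Realises the generative model: each channel is the subject's lognormal
#' gain, times a per-channel lognormal contact-gain jitter, times a sum of
#' independent band-limited oscillations (amplitudes boosted by
#' `1 + effect_size` at effect channels/bands in condition II),
#' plus a 1/f background, plus artifacts — Hann-shaped blink bumps (~0.3 s,
#' frontal channels only), electrode-pop step discontinuities on one random
#' channel each, and a common 50 Hz mains sinusoid.
#'
#' @param config A [synth_config()].
#' @param subject_id Subject identifier.
#' @param condition `"I"` or `"II"`.
#' @param rng_seed Seed for this recording's RNG stream. If `NULL`
#'   (default), derived from `config$seed`, the subject and the condition —
#'   the subject's gain is always derived from `config$seed` and subject
#'   only, so both of a subject's recordings share one gain.
#' @param ground_truth Attach the artifact ground truth (blink/pop times,
#'   line phase) as attribute `"ground_truth"`? Default TRUE.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(config, subject_id, condition,
                               rng_seed = NULL, ground_truth = TRUE) {
  if (!condition %in% c("I", "II")) {
    stop("condition must be 'I' or 'II', got '", condition, "'",
         call. = FALSE)
  }
  mont <- montage_channels()
  bands <- band_definitions()
  n <- round(config$duration_s * config$fs_hz)
  subj_idx <- subject_index(subject_id)
  cond_idx <- match(condition, c("I", "II"))
  seed <- rng_seed %||% derive_seed(config$seed, 7L, subj_idx, cond_idx)

  # Subject gain: same for both conditions of a subject by construction.
  gain <- with_local_seed(
    derive_seed(config$seed, 11L, subj_idx),
    stats::rlnorm(1, meanlog = 0, sdlog = config$subject_gain_sd)
  )
  # Channel gain jitter: electrode-contact variability, independent per
  # recording and channel.
  ch_gain <- with_local_seed(
    derive_seed(seed, 19L),
    stats::rlnorm(nrow(mont), meanlog = 0, sdlog = config$channel_gain_sd)
  )

  neural <- matrix(0, nrow(mont), n)
  for (ci in seq_len(nrow(mont))) {
    for (bi in seq_len(nrow(bands))) {
      amp <- config$base_band_amplitude[[bands$band[bi]]]
      if (amp <= 0) next
      boosted <- condition == "II" &&
        mont$channel[ci] %in% config$effect_channels &&
        bands$band[bi] %in% config$effect_bands
      if (boosted) amp <- amp * (1 + config$effect_size)
      osc <- generate_band_oscillation(
        bands[bi, ], n, config$fs_hz,
        rng_seed = derive_seed(seed, 13L, ci, bi)
      )
      neural[ci, ] <- neural[ci, ] + amp * osc
    }
  }
  neural <- gain * ch_gain * neural

  truth <- list(blink = NULL, pops = NULL, line_phase = NA_real_)
  data <- with_local_seed(derive_seed(seed, 17L), {
    out <- neural
    for (ci in seq_len(nrow(mont))) {
      out[ci, ] <- out[ci, ] +
        pink_noise(n, config$fs_hz, config$pink_noise_amplitude)
    }
    # Blinks: shared waveform on the four frontal channels.
    if (config$blink_rate_hz > 0 && config$blink_amplitude > 0) {
      n_blinks <- stats::rpois(1, config$blink_rate_hz * n / config$fs_hz)
      width <- max(3L, round(0.3 * config$fs_hz))
      track <- numeric(n)
      starts <- integer(0)
      if (n_blinks > 0 && n > width) {
        starts <- sort(sample.int(n - width, n_blinks, replace = TRUE))
        bump <- blink_bump(width)
        for (s in starts) {
          idx <- s:(s + width - 1)
          track[idx] <- track[idx] + config$blink_amplitude * bump
        }
      }
      truth$blink <- list(starts = starts, width = width, track = track)
      fr <- match(frontal_channels(), mont$channel)
      out[fr, ] <- sweep(out[fr, , drop = FALSE], 2, track, `+`)
    }
    # Electrode pops: step discontinuity on one random channel each.
    if (config$pop_rate_hz > 0 && config$pop_amplitude > 0) {
      n_pops <- stats::rpois(1, config$pop_rate_hz * n / config$fs_hz)
      if (n_pops > 0) {
        chs <- sample.int(nrow(mont), n_pops, replace = TRUE)
        ats <- sample.int(n, n_pops, replace = TRUE)
        sgn <- sample(c(-1, 1), n_pops, replace = TRUE)
        for (p in seq_len(n_pops)) {
          out[chs[p], ats[p]:n] <- out[chs[p], ats[p]:n] +
            sgn[p] * config$pop_amplitude
        }
        truth$pops <- data.frame(channel = mont$channel[chs],
                                 at = ats, sign = sgn)
      }
    }
    # Mains line: common-phase 50 Hz on every channel.
    if (config$line_noise_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      tt <- (0:(n - 1)) / config$fs_hz
      line <- config$line_noise_amplitude * sin(2 * pi * 50 * tt + phase)
      out <- sweep(out, 2, line, `+`)
      truth$line_phase <- phase
    }
    out
  })

  rec <- eeg_recording(data, subject_id, condition, config$fs_hz)
  if (ground_truth) {
    truth$gain <- gain
    attr(rec, "ground_truth") <- truth
  }
  rec
}

# Map arbitrary subject ids to a stable integer for seed derivation.
subject_index <- function(subject_id) {
  id <- as.character(subject_id)
  num <- suppressWarnings(as.integer(gsub("\\D", "", id)))
  if (!is.na(num)) return(num)
  sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 1000003L
}

#' Generate a full synthetic cohort
#'
#' Every subject appears once per condition; per-recording seeds derive
#' deterministically from `config$seed`, the subject index and the
#' condition, so identical configs give byte-identical cohorts.
#'
#' @param config A [synth_config()] with `n_subjects >= 2`.
#' @return A list of `2 * n_subjects` [eeg_recording()] objects, ordered
#'   subject-major (S1/I, S1/II, S2/I, ...).
#' @examples
#' cohort <- generate_cohort(synth_config(n_subjects = 2, duration_s = 1))
#' length(cohort)
#' @export
generate_cohort <- function(config) {
  if (config$n_subjects < 2) {
    stop("n_subjects must be >= 2: a single subject admits no ",
         "between-group contrast", call. = FALSE)
  }
  recs <- vector("list", 2L * config$n_subjects)
  i <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (cond in c("I", "II")) {
      i <- i + 1L
      recs[[i]] <- generate_recording(config, sprintf("S%02d", s), cond)
    }
  }
  recs
}
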