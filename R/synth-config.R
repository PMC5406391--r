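#' Configuration for the synthetic EEG cohort generator
#'
#' Bundles every knob of the simulated listening study: cohort size, trial
#' duration and sampling rate, per-band oscillation amplitudes on top of a
#' 1/f (pink) background, the channels and bands carrying the
#' condition-II power boost, between-subject gain variability, and the
#' artifact model (blinks, electrode pops, mains line).
#'
#' The defaults emulate the study design the pipeline targets: 20 subjects,
#' each contributing one 2-minute trial per listening condition at 128 Hz
#' over the 14-channel montage, with the condition-II (Mozart / bipartite)
#' boost confined to the theta and alpha bands at channels
#' F3, F4, P8, O2 and T7.
#'
#' @param n_subjects Number of subjects; each yields one recording per
#'   condition. Default 20.
#' @param duration_s Trial duration in seconds. Default 120.
#' @param fs_hz Sampling rate in Hz; must exceed twice the highest band
#'   edge. Default 128.
#' @param base_band_amplitude Named numeric vector of per-band oscillation
#'   standard deviations (signal units), names `theta`, `alpha`, `beta`,
#'   `gamma`. Defaults fall off with frequency like real EEG.
#' @param pink_noise_amplitude Standard deviation of the 1/f background.
#' @param effect_channels Channels receiving the condition-II amplitude
#'   boost. Default `c("F3","F4","P8","O2","T7")`.
#' @param effect_bands Bands receiving the boost. Default theta and alpha.
#' @param effect_size Fractional amplitude boost `delta >= 0` applied in
#'   condition II at effect channels/bands; band power scales by
#'   `(1 + delta)^2`. Default 0.5.
#' @param subject_gain_sd Standard deviation (log scale) of the per-subject
#'   lognormal gain multiplying the oscillatory part of every channel.
#' @param channel_gain_sd Standard deviation (log scale) of the
#'   per-recording, per-channel lognormal gain jitter emulating
#'   electrode-contact variability between sessions and sites.
#' @param blink_rate_hz Poisson rate of blink bumps (frontal channels only).
#' @param blink_amplitude Peak amplitude of one blink bump (signal units).
#' @param pop_rate_hz Poisson rate of electrode-pop step discontinuities.
#' @param pop_amplitude Step size of one electrode pop.
#' @param line_noise_amplitude Amplitude of the 50 Hz mains sinusoid added
#'   to every channel. Set any artifact rate/amplitude to 0 to disable it.
#' @param seed Integer base seed; every recording's RNG stream is derived
#'   deterministically from it.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @examples
#' cfg <- synth_config(n_subjects = 4, duration_s = 2)
#' cfg$effect_channels
#' @export
synth_config <- function(n_subjects = 20,
                         duration_s = 120,
                         fs_hz = 128,
                         base_band_amplitude = c(theta = 4, alpha = 3,
                                                 beta = 2, gamma = 1),
                         pink_noise_amplitude = 2,
                         effect_channels = c("F3", "F4", "P8", "O2", "T7"),
                         effect_bands = c("theta", "alpha"),
                         effect_size = 0.5,
                         subject_gain_sd = 0.1,
                         channel_gain_sd = 0.2,
                         blink_rate_hz = 0.25,
                         blink_amplitude = 30,
                         pop_rate_hz = 0.02,
                         pop_amplitude = 25,
                         line_noise_amplitude = 1,
                         seed = 20170427) {
  bands <- band_definitions()
  stopifnot(n_subjects >= 1, duration_s > 0, fs_hz > 0)
  if (fs_hz <= 2 * max(bands$hi_hz)) {
    stop("fs_hz must exceed twice the highest band edge (",
         2 * max(bands$hi_hz), " Hz)", call. = FALSE)
  }
  if (!all(bands$band %in% names(base_band_amplitude))) {
    stop("base_band_amplitude must be named for all of: ",
         paste(bands$band, collapse = ", "), call. = FALSE)
  }
  amps <- c(base_band_amplitude[bands$band])
  rates <- c(pink_noise_amplitude, effect_size, subject_gain_sd,
             channel_gain_sd, blink_rate_hz, blink_amplitude, pop_rate_hz, pop_amplitude,
             line_noise_amplitude)
  if (any(amps < 0) || any(rates < 0)) {
    stop("amplitudes, rates and effect_size must all be >= 0", call. = FALSE)
  }
  bad <- setdiff(effect_channels, montage_channels()$channel)
  if (length(bad) > 0) {
    stop("effect_channels not in montage: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(effect_bands, bands$band)
  if (length(bad) > 0) {
    stop("effect_bands not canonical: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      duration_s = duration_s,
      fs_hz = fs_hz,
      base_band_amplitude = amps,
      pink_noise_amplitude = pink_noise_amplitude,
      effect_channels = effect_channels,
      effect_bands = effect_bands,
      effect_size = effect_size,
      subject_gain_sd = subject_gain_sd,
      channel_gain_sd = channel_gain_sd,
      blink_rate_hz = blink_rate_hz,
      blink_amplitude = blink_amplitude,
      pop_rate_hz = pop_rate_hz,
      pop_amplitude = pop_amplitude,
      line_noise_amplitude = line_noise_amplitude,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  cohort: %d subjects x 2 conditions, %.4g s @ %g Hz\n",
              x$n_subjects, x$duration_s, x$fs_hz))
  cat(sprintf("  band sd: %s; pink sd %.3g; gain sd subject %.3g / channel %.3g\n",
              paste(sprintf("%s=%.3g", names(x$base_band_amplitude),
                            x$base_band_amplitude), collapse = " "),
              x$pink_noise_amplitude, x$subject_gain_sd, x$channel_gain_sd))
  cat(sprintf("  effect: +%.0f%% amplitude in {%s} x {%s} (condition II)\n",
              100 * x$effect_size,
              paste(x$effect_channels, collapse = ","),
              paste(x$effect_bands, collapse = ",")))
  cat(sprintf("  artifacts: blink %.3g/s (amp %.3g), pop %.3g/s (amp %.3g), line 50 Hz amp %.3g\n",
              x$blink_rate_hz, x$blink_amplitude, x$pop_rate_hz,
              x$pop_amplitude, x$line_noise_amplitude))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Turn off all artifact sources in a config
#'
#' Convenience for tests and statistical suites that need the pure
#' oscillation-plus-pink-noise model.
#'
#' @param config A [synth_config()].
#' @param pink_noise Also zero the 1/f background? Default FALSE.
#' @return The modified config.
#' @export
without_artifacts <- function(config, pink_noise = FALSE) {
  config$blink_rate_hz <- 0
  config$pop_rate_hz <- 0
  config$line_noise_amplitude <- 0
  if (pink_noise) config$pink_noise_amplitude <- 0
  config
}

#' Write / read a synth_config as a plain-text key-value file
#'
#' Round-trips every field losslessly. Vector fields are comma-separated;
#' the named band amplitudes serialize as `band=value` pairs.
#'
#' @param config A [synth_config()].
#' @param path File path.
#' @return `write_synth_config` returns `path` invisibly;
#'   `read_synth_config` returns a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  fmt_num <- function(v) paste(format(v, digits = 17, scientific = FALSE,
                                      trim = TRUE), collapse = ",")
  lines <- c(
    paste0("n_subjects: ", config$n_subjects),
    paste0("duration_s: ", fmt_num(config$duration_s)),
    paste0("fs_hz: ", fmt_num(config$fs_hz)),
    paste0("base_band_amplitude: ",
           paste(sprintf("%s=%s", names(config$base_band_amplitude),
                         vapply(config$base_band_amplitude, fmt_num, "")),
                 collapse = ",")),
    paste0("pink_noise_amplitude: ", fmt_num(config$pink_noise_amplitude)),
    paste0("effect_channels: ", paste(config$effect_channels, collapse = ",")),
    paste0("effect_bands: ", paste(config$effect_bands, collapse = ",")),
    paste0("effect_size: ", fmt_num(config$effect_size)),
    paste0("subject_gain_sd: ", fmt_num(config$subject_gain_sd)),
    paste0("channel_gain_sd: ", fmt_num(config$channel_gain_sd)),
    paste0("blink_rate_hz: ", fmt_num(config$blink_rate_hz)),
    paste0("blink_amplitude: ", fmt_num(config$blink_amplitude)),
    paste0("pop_rate_hz: ", fmt_num(config$pop_rate_hz)),
    paste0("pop_amplitude: ", fmt_num(config$pop_amplitude)),
    paste0("line_noise_amplitude: ", fmt_num(config$line_noise_amplitude)),
    paste0("seed: ", config$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = ":"), "")
  get_val <- function(k) vals[match(k, keys)]
  amp_pairs <- strsplit(strsplit(get_val("base_band_amplitude"), ",")[[1]], "=")
  amps <- stats::setNames(
    vapply(amp_pairs, function(p) as.numeric(p[2]), 0),
    vapply(amp_pairs, `[`, "", 1)
  )
  synth_config(
    n_subjects = as.integer(get_val("n_subjects")),
    duration_s = as.numeric(get_val("duration_s")),
    fs_hz = as.numeric(get_val("fs_hz")),
    base_band_amplitude = amps,
    pink_noise_amplitude = as.numeric(get_val("pink_noise_amplitude")),
    effect_channels = strsplit(get_val("effect_channels"), ",")[[1]],
    effect_bands = strsplit(get_val("effect_bands"), ",")[[1]],
    effect_size = as.numeric(get_val("effect_size")),
    subject_gain_sd = as.numeric(get_val("subject_gain_sd")),
    channel_gain_sd = as.numeric(get_val("channel_gain_sd")),
    blink_rate_hz = as.numeric(get_val("blink_rate_hz")),
    blink_amplitude = as.numeric(get_val("blink_amplitude")),
    pop_rate_hz = as.numeric(get_val("pop_rate_hz")),
    pop_amplitude = as.numeric(get_val("pop_amplitude")),
    line_noise_amplitude = as.numeric(get_val("line_noise_amplitude")),
    seed = as.integer(get_val("seed"))
  )
}
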