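test_that("band oscillations are unit-variance, band-confined and seeded", {
  x <- generate_band_oscillation("alpha", 15360, 128, rng_seed = 1)
  expect_length(x, 15360)
  expect_equal(var(x), 1, tolerance = 1e-10)

  sp <- compute_spectrum(x, 128)
  concentration <- band_power(sp, "alpha") / sum(sp$power)
  expect_gte(concentration, 0.95)

  expect_identical(x, generate_band_oscillation("alpha", 15360, 128,
                                                rng_seed = 1))
  y <- generate_band_oscillation("alpha", 15360, 128, rng_seed = 2)
  expect_lt(abs(cor(x, y)), 0.2)

  expect_error(generate_band_oscillation("theta", 0, 128, rng_seed = 1),
               "empty")
  bad <- tibble::tibble(band = "x", lo_hz = 60, hi_hz = 70)
  expect_error(generate_band_oscillation(bad, 1024, 128, rng_seed = 1),
               "Nyquist")
})

test_that("every canonical band stays confined at mini-cohort lengths", {
  for (b in band_definitions()$band) {
    x <- generate_band_oscillation(b, 120, 128, rng_seed = 3)
    sp <- compute_spectrum(x, 128)
    expect_gte(band_power(sp, b) / sum(sp$power), 0.95)
  }
})

test_that("recordings have the study geometry and validated metadata", {
  cfg <- synth_config()
  rec <- generate_recording(cfg, "S01", "II")
  expect_s3_class(rec, "eeg_recording")
  expect_identical(dim(rec$data), c(14L, 15360L))
  expect_identical(rownames(rec$data), montage_channels()$channel)
  expect_true(all(is.finite(rec$data)))
  expect_error(generate_recording(cfg, "S01", "III"), "condition")
})

test_that("condition II boosts effect-band power relative to condition I", {
  diffs <- vapply(1:20, function(s) {
    cfg <- mini_config(seed = 1000 + s, effect_size = 0.5, duration_s = 4)
    r1 <- generate_recording(cfg, "S01", "I")
    r2 <- generate_recording(cfg, "S01", "II")
    f4 <- which(montage_channels()$channel == "F4")
    p1 <- band_power(compute_spectrum(r1$data[f4, ], 128), "alpha")
    p2 <- band_power(compute_spectrum(r2$data[f4, ], 128), "alpha")
    log(p2 / p1)
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("a null generator leaves the two conditions exchangeable", {
  cfg0 <- mini_config(seed = 7, effect_size = 0, duration_s = 2)
  p1 <- p2 <- numeric(50)
  f4 <- which(montage_channels()$channel == "F4")
  for (s in 1:50) {
    cfg0$seed <- 5000L + s
    r1 <- generate_recording(cfg0, "S01", "I")
    r2 <- generate_recording(cfg0, "S02", "II")
    p1[s] <- band_power(compute_spectrum(r1$data[f4, ], 128), "alpha")
    p2[s] <- band_power(compute_spectrum(r2$data[f4, ], 128), "alpha")
  }
  # log powers are comparable in location and pass a two-sample test
  expect_gt(t.test(log(p1), log(p2))$p.value, 0.01)
  expect_lt(abs(mean(log(p2)) - mean(log(p1))), 0.3)
})

test_that("cohorts enumerate subject x condition deterministically", {
  cfg <- mini_config(seed = 11, duration_s = 1, n_subjects = 20)
  cohort <- cached_fm("cohort20x1s", function() generate_cohort(cfg))
  expect_length(cohort, 40)
  meta <- vapply(cohort, function(r) paste(r$subject_id, r$condition), "")
  expect_identical(anyDuplicated(meta), 0L)
  expect_setequal(vapply(cohort, function(r) r$condition, ""), c("I", "II"))

  small <- generate_cohort(mini_config(seed = 11, duration_s = 1,
                                       n_subjects = 2))
  expect_length(small, 4)
  expect_setequal(vapply(small, function(r) r$subject_id, ""),
                  c("S01", "S02"))

  again <- generate_cohort(mini_config(seed = 11, duration_s = 1,
                                       n_subjects = 2))
  expect_identical(lapply(small, function(r) r$data),
                   lapply(again, function(r) r$data))

  expect_error(generate_cohort(mini_config(1, n_subjects = 1)),
               "n_subjects")
})

test_that("subjects keep one gain across conditions; channels jitter per recording", {
  cfg <- mini_config(seed = 13, duration_s = 1)
  r1 <- generate_recording(cfg, "S05", "I")
  r2 <- generate_recording(cfg, "S05", "II")
  expect_identical(attr(r1, "ground_truth")$gain,
                   attr(r2, "ground_truth")$gain)
})

test_that("with noise and gains off, variance adds across bands", {
  cfg <- synth_config(duration_s = 8, subject_gain_sd = 0,
                      channel_gain_sd = 0, pink_noise_amplitude = 0,
                      seed = 17)
  cfg <- without_artifacts(cfg)
  rec <- generate_recording(cfg, "S01", "I")
  expected <- sum(cfg$base_band_amplitude^2)
  observed <- mean(apply(rec$data, 1, var))
  expect_equal(observed, expected, tolerance = 0.05)
})

test_that("band-power ratio between conditions estimates (1+delta)^2", {
  delta <- 0.5
  f4 <- which(montage_channels()$channel == "F4")
  p7 <- which(montage_channels()$channel == "P7")   # non-effect channel
  lr_eff <- lr_null <- numeric(200)
  for (s in 1:200) {
    cfg <- mini_config(seed = 20000 + s, effect_size = delta,
                       duration_s = 2)
    cfg$subject_gain_sd <- 0
    cfg$channel_gain_sd <- 0
    rI <- generate_recording(cfg, "S01", "I")
    rII <- generate_recording(cfg, "S01", "II")
    bp <- function(r, ch) band_power(compute_spectrum(r$data[ch, ], 128),
                                     "alpha")
    lr_eff[s] <- log(bp(rII, f4) / bp(rI, f4))
    lr_null[s] <- log(bp(rII, p7) / bp(rI, p7))
  }
  expect_equal(exp(mean(lr_eff)), (1 + delta)^2, tolerance = 0.1)
  expect_equal(exp(mean(lr_null)), 1, tolerance = 0.1)
})

test_that("blinks land only on frontal channels and pops step one channel", {
  cfg <- synth_config(n_subjects = 2, duration_s = 8, seed = 23,
                      blink_rate_hz = 0.5, pop_rate_hz = 0,
                      line_noise_amplitude = 0, pink_noise_amplitude = 0)
  rec <- generate_recording(cfg, "S01", "I")
  gt <- attr(rec, "ground_truth")
  expect_gt(length(gt$blink$starts), 0)
  # Frontal channels carry the blink track, others do not: correlation
  # with the known track is high only frontally.
  track <- gt$blink$track
  cors <- apply(rec$data, 1, function(ch) cor(ch, track))
  frontal <- montage_channels()$channel %in% c("AF3", "AF4", "F7", "F8")
  expect_true(all(cors[frontal] > 0.5))
  expect_true(all(abs(cors[!frontal]) < 0.3))
})
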