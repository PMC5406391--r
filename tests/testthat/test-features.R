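# Independent oracle: literal O(n^2) DFT.
direct_dft_power <- function(x) {
  n <- length(x)
  k <- 0:floor(n / 2)
  vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))^2
  }, 0)
}

test_that("compute_spectrum matches a direct DFT oracle", {
  set.seed(42)
  for (n in c(17, 64, 128)) {
    x <- rnorm(n)
    sp <- compute_spectrum(x, 128)
    expect_equal(sp$power, direct_dft_power(x), tolerance = 1e-9)
    expect_equal(sp$freqs_hz, (0:floor(n / 2)) * 128 / n)
  }
})

test_that("a bin-aligned sinusoid concentrates in a single bin", {
  n <- 1024
  x <- sin(2 * pi * 8 * (0:(n - 1)) / 128)    # 8 Hz is bin 64 exactly
  sp <- compute_spectrum(x, 128)
  non_dc <- sp$power[-1]
  peak <- which.max(non_dc)
  expect_equal(sp$freqs_hz[peak + 1], 8)
  expect_gte(non_dc[peak] / sum(non_dc), 0.999)
  expect_gte(band_power(sp, "alpha") / sum(non_dc), 0.999)
})

test_that("spectrum handles degenerate inputs", {
  sp <- compute_spectrum(numeric(16), 128)
  expect_true(all(sp$power == 0))
  expect_error(compute_spectrum(numeric(0), 128), "at least 2")
  expect_error(compute_spectrum(1, 128), "at least 2")
  expect_error(compute_spectrum(c(1, NA, 3), 128), "finite")
})

test_that("Parseval's identity holds under the one-sided convention", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(c(1000, 4096, 4097), 1)
    x <- rnorm(n)
    sp <- compute_spectrum(x, 128)
    w <- phraseeg:::parseval_weights(sp)
    lhs <- sum(w * sp$power)
    rhs <- n * sum(x^2)
    expect_lt(abs(lhs - rhs) / rhs, 1e-6)
  }
})

test_that("band_power sums inclusive band edges and is additive", {
  sp <- structure(
    list(freqs_hz = c(0, 4, 7, 10, 15, 16, 45),
         power = c(1, 2, 3, 4, 5, 6, 7), n = 128, fs_hz = 128),
    class = "eeg_spectrum")
  expect_equal(band_power(sp, "theta"), 5)       # bins at 4 and 7 included
  expect_equal(band_power(sp, "alpha"), 9)       # 10 and 15
  expect_equal(band_power(sp, "beta"), 6)
  expect_equal(band_power(sp, "gamma"), 7)
  total_in_bands <- sum(vapply(band_definitions()$band,
                               function(b) band_power(sp, b), 0))
  expect_lte(total_in_bands, sum(sp$power))
  expect_error(band_power(sp, tibble::tibble(band = "x", lo_hz = 10,
                                             hi_hz = 70)),
               "outside")

  one_bin <- structure(
    list(freqs_hz = c(0, 10), power = c(0, 4), n = 64, fs_hz = 128),
    class = "eeg_spectrum")
  expect_equal(band_power(one_bin, "alpha"), 4)
  expect_equal(band_power(one_bin, "theta"), 0)
})

test_that("feature matrix has the study geometry and fixed column order", {
  fm <- cached_fm("fm20x1s_null", function() {
    build_feature_matrix(cached_fm("cohort20x1s", function() {
      generate_cohort(mini_config(seed = 11, duration_s = 1,
                                  n_subjects = 20))
    }))
  })
  expect_identical(nrow(fm), 40L)
  expect_length(feature_columns(fm), 56)
  meta <- attr(fm, "col_meta")
  expect_identical(meta$channel, rep(montage_channels()$channel, each = 4))
  expect_identical(meta$band, rep(band_definitions()$band, 14))
  expect_true(all(as.matrix(fm[, feature_columns(fm)]) >= 0))

  # single band, two recordings
  cfg <- mini_config(seed = 3, duration_s = 1, n_subjects = 2)
  two <- list(generate_recording(cfg, "S01", "I"),
              generate_recording(cfg, "S01", "II"))
  fm1 <- build_feature_matrix(two, bands = band_definitions()[1, ])
  expect_identical(nrow(fm1), 2L)
  expect_length(feature_columns(fm1), 14)

  # column order is a pure function of montage and bands
  fm2 <- build_feature_matrix(two, bands = band_definitions()[1, ])
  expect_identical(feature_columns(fm1), feature_columns(fm2))
})

test_that("feature matrix validates montage and condition coverage", {
  cfg <- mini_config(seed = 3, duration_s = 1, n_subjects = 2)
  a <- generate_recording(cfg, "S01", "I")
  b <- generate_recording(cfg, "S01", "II")
  b2 <- b; b2$fs_hz <- 256
  expect_error(build_feature_matrix(list(a, b2)), "sampling rate")
  expect_error(build_feature_matrix(list(a, a)), "per condition")
  expect_error(build_feature_matrix(list()), "no recordings")
})

test_that("features scale as amplitude squared", {
  cfg <- mini_config(seed = 5, duration_s = 1, n_subjects = 2)
  recs <- generate_cohort(cfg)
  fm <- build_feature_matrix(recs)
  k <- 3
  recs_k <- lapply(recs, function(r) { r$data <- k * r$data; r })
  fm_k <- build_feature_matrix(recs_k)
  cols <- feature_columns(fm)
  expect_equal(as.matrix(fm_k[, cols]), k^2 * as.matrix(fm[, cols]),
               tolerance = 1e-10)
})

test_that("features_long tidies to one row per subject x condition x feature", {
  fm <- mini_cohort_features(seed = 5, duration_s = 1, n_subjects = 2)
  long <- features_long(fm)
  expect_identical(nrow(long), 4L * 56L)
  expect_setequal(unique(long$band), band_definitions()$band)
  # round-trip sum check
  expect_equal(sum(long$power), sum(as.matrix(fm[, feature_columns(fm)])))
})
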