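#' Configuration for an end-to-end pipeline run
#'
#' Bundles the synthetic-cohort settings with every downstream stage's
#' knobs. All stage seeds derive deterministically from `base_seed`, so a
#' single integer reproduces every number in every output file.
#'
#' @param synthetic A [synth_config()] (its `seed` is overridden by
#'   `base_seed`).
#' @param preprocess Run the preprocessing stage? Default TRUE.
#' @param baseline_cutoff_hz High-pass drift cutoff. Default 0.5.
#' @param ica ICA artifact rejection on? Default TRUE.
#' @param adaptive LMS adaptive cancellation on? Default FALSE (the stage
#'   needs a noise reference; when on, the generator's known 50 Hz track
#'   frequency is used to synthesize one).
#' @param k,repeats Cross-validation controls. Defaults 10, 10.
#' @param family_alpha Familywise level. Default 0.05.
#' @param n_comparisons Bonferroni divisor. Default 14.
#' @param variance_target PCA retention target. Default 0.95.
#' @param min_node_fraction Tree stopping fraction. Default 0.2.
#' @param paper_mode Pooled selection + PCA protocol? Default FALSE.
#' @param base_seed Integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synth_config(),
                            preprocess = TRUE,
                            baseline_cutoff_hz = 0.5,
                            ica = TRUE,
                            adaptive = FALSE,
                            k = 10, repeats = 10,
                            family_alpha = 0.05, n_comparisons = 14,
                            variance_target = 0.95,
                            min_node_fraction = 0.2,
                            paper_mode = FALSE,
                            base_seed = 20170427) {
  synthetic$seed <- as.integer(base_seed)
  structure(
    list(synthetic = synthetic, preprocess = preprocess,
         baseline_cutoff_hz = baseline_cutoff_hz, ica = ica,
         adaptive = adaptive, k = k, repeats = repeats,
         family_alpha = family_alpha, n_comparisons = n_comparisons,
         variance_target = variance_target,
         min_node_fraction = min_node_fraction,
         paper_mode = paper_mode, base_seed = as.integer(base_seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) a cohort, preprocess it, extract the
#' spectral-power feature matrix, compute the per-feature statistics
#' tables, run the cross-validated PCA + tree classifier, and write every
#' artifact to a directory: `features.csv`, `stats_theta.csv` ...
#' `stats_gamma.csv`, `report.json`, `topo.json` and `run.log`.
#' Re-running with the same config reproduces all numeric outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param recordings Optional pre-loaded list of recordings (e.g. from
#'   [ingest_recordings()]); skips the simulation stage.
#' @return Invisibly, a list with the in-memory artifacts: `features`,
#'   `stats` (per-band tibbles), `report`, `topo`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, recordings = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
    invisible(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      say("[%s] FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say("[%s] done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  say("pipeline run, base seed %d", config$base_seed)
  if (is.null(recordings)) {
    recordings <- stage("simulate", generate_cohort(config$synthetic))
    say("[simulate] %d recordings (%d subjects x 2 conditions)",
        length(recordings), config$synthetic$n_subjects)
  } else {
    say("[ingest] %d recordings supplied", length(recordings))
  }

  if (config$preprocess) {
    recordings <- stage("preprocess", {
      purrr::imap(recordings, function(rec, i) {
        ref <- NULL
        if (config$adaptive) {
          tt <- (0:(n_samples(rec) - 1)) / rec$fs_hz
          ref <- sin(2 * pi * 50 * tt)
        }
        preprocess_recording(
          rec, baseline_cutoff_hz = config$baseline_cutoff_hz,
          ica = config$ica,
          rng_seed = derive_seed(config$base_seed, 37L, i),
          adaptive_reference = ref)
      })
    })
    flagged <- purrr::map(recordings,
                          ~ attr(.x, "flagged_components") %||% integer(0))
    say("[preprocess] ICA components removed per recording: %s",
        paste(lengths(flagged), collapse = ""))
  }

  features <- stage("features", build_feature_matrix(recordings))
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  say("[features] matrix %d x %d", nrow(features),
      length(feature_columns(features)))

  stats_tbl <- stage("stats", stats_table(
    features, k = config$k, repeats = config$repeats,
    rng_seed = derive_seed(config$base_seed, 41L),
    family_alpha = config$family_alpha,
    n_comparisons = config$n_comparisons))
  per_band <- split(stats_tbl, stats_tbl$band)
  for (b in names(per_band)) {
    tbl <- per_band[[b]] |>
      dplyr::select("channel", "rho", "se_pct", "sp_pct", "acc_pct",
                    "significant")
    utils::write.csv(tbl, file.path(out_dir, sprintf("stats_%s.csv", b)),
                     row.names = FALSE)
  }
  say("[stats] %d significant features at alpha = %.5f",
      sum(stats_tbl$significant), attr(stats_tbl, "bonferroni_alpha"))

  report <- stage("classify", cross_validated_classify(
    features, k = config$k, repeats = config$repeats,
    rng_seed = derive_seed(config$base_seed, 43L),
    variance_target = config$variance_target,
    min_node_fraction = config$min_node_fraction,
    family_alpha = config$family_alpha,
    n_comparisons = config$n_comparisons,
    paper_mode = config$paper_mode))
  jsonlite::write_json(
    list(n_components = report$n_components,
         confusion = report$confusion,
         confusion_normalized = report$confusion_normalized,
         global_acc_pct = report$global_acc_pct,
         se_pct = report$se_pct, sp_pct = report$sp_pct,
         settings = report$settings),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  say("[classify] global accuracy %.2f%%", report$global_acc_pct)

  topo <- stage("report", {
    purrr::map(band_names(), ~ summarize_topography(features, .x))
  })
  names(topo) <- band_names()
  jsonlite::write_json(topo, file.path(out_dir, "topo.json"),
                       auto_unbox = TRUE, digits = NA)
  say("pipeline complete")

  invisible(list(features = features, stats = stats_tbl, report = report,
                 topo = topo, out_dir = out_dir))
}

#' Per-channel group-average power summary (topographic view)
#'
#' For one band, the mean spectral power of every channel within each
#' condition group — the numbers behind a per-channel scalp map — joined
#' with the montage coordinates for rendering.
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param band Band name.
#' @return A tibble of class `eeg_topo` with columns `channel`, `x`, `y`,
#'   `band`, `group_I`, `group_II`.
#' @export
summarize_topography <- function(features, band) {
  if (is.character(band) && length(band) == 1) band <- band_definition(band)
  if (!all(c("I", "II") %in% features$condition)) {
    stop("both condition groups must be present", call. = FALSE)
  }
  long <- features_long(features) |>
    dplyr::filter(.data$band == !!band$band) |>
    dplyr::group_by(.data$channel, .data$band) |>
    dplyr::summarise(
      group_I = mean(.data$power[.data$condition == "I"]),
      group_II = mean(.data$power[.data$condition == "II"]),
      .groups = "drop")
  out <- montage_channels() |> dplyr::inner_join(long, by = "channel")
  class(out) <- c("eeg_topo", class(out))
  out
}

#' Interpolate a topographic summary onto a unit-circle grid
#'
#' Inverse-distance-weighted interpolation of per-channel values; the
#' surface equals the channel value exactly at each electrode location.
#'
#' @param topo An `eeg_topo` tibble from [summarize_topography()].
#' @param value Column to interpolate (`"group_I"`, `"group_II"` or a
#'   difference computed by the caller).
#' @param n_grid Grid resolution per axis. Default 40.
#' @param power IDW exponent. Default 2.
#' @return A tibble with `x`, `y`, `value` for grid points inside the
#'   unit circle.
#' @export
interpolate_topography <- function(topo, value = "group_II", n_grid = 40,
                                   power = 2) {
  g <- seq(-1, 1, length.out = n_grid)
  grid <- expand.grid(x = g, y = g)
  grid <- grid[grid$x^2 + grid$y^2 <= 1, ]
  vals <- topo[[value]]
  interp <- vapply(seq_len(nrow(grid)), function(i) {
    d2 <- (grid$x[i] - topo$x)^2 + (grid$y[i] - topo$y)^2
    hit <- which(d2 < 1e-12)
    if (length(hit) > 0) return(vals[hit[1]])
    w <- 1 / d2^(power / 2)
    sum(w * vals) / sum(w)
  }, 0)
  tibble::tibble(x = grid$x, y = grid$y, value = interp)
}
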