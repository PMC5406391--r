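# Shared fixtures, built in code. Mini cohorts keep the full study design
# (20 subjects x 2 conditions, 14 channels) but shorten each trial.

mini_config <- function(seed, effect_size = 0, duration_s = 120 / 128,
                        n_subjects = 20, artifacts = FALSE) {
  cfg <- synth_config(n_subjects = n_subjects, duration_s = duration_s,
                      effect_size = effect_size, seed = seed)
  if (!artifacts) cfg <- without_artifacts(cfg)
  cfg
}

mini_cohort_features <- function(seed, effect_size = 0, duration_s = 120 / 128,
                                 n_subjects = 20, artifacts = FALSE) {
  build_feature_matrix(generate_cohort(
    mini_config(seed, effect_size, duration_s, n_subjects, artifacts)))
}

# A cached 4 s / 20-subject null cohort reused by several suites.
cached_fm <- local({
  cache <- new.env(parent = emptyenv())
  function(key, maker) {
    if (is.null(cache[[key]])) cache[[key]] <- maker()
    cache[[key]]
  }
})
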