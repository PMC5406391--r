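Package: phraseeg
Title: Band-Power Analysis and Classification of EEG Responses to Musical
    Phrase Rhythm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 14-channel consumer-grade EEG recordings of
    listeners exposed to two contrasting musical phrase structures. Provides a
    seeded synthetic cohort generator (band-limited oscillations on a 1/f
    background with blink, electrode-pop and mains-line artifacts), zero-phase
    FIR preprocessing with ICA-based artifact rejection, FFT spectral-power
    feature extraction over the canonical theta/alpha/beta/gamma bands,
    per-channel ANOVA statistics with Bonferroni correction, repeated
    stratified cross-validated single-feature ROC thresholding, and a
    PCA-plus-Gini-decision-tree group classifier, together with tabular and
    topographic summaries of the results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
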