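# phraseeg

EEG band-power analysis and classification of listener responses to two
contrasting musical phrase structures (a rondo-form movement, condition I,
versus a bipartite sonata movement, condition II). The package is for
researchers who want the full analysis chain of such a listening study as
reusable, tested R code: a seeded synthetic cohort generator standing in
for the (undeposited) raw recordings, zero-phase FIR preprocessing with
ICA artifact rejection, FFT spectral-power features, per-channel ANOVA
statistics with Bonferroni correction, cross-validated single-feature ROC
scoring, and a PCA + decision-tree group classifier.

## The method

Fourteen 10–20-system channels (AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8,
FC6, F4, F8, AF4) are recorded at 128 Hz for ~2 minutes per condition from
20 subjects. After drift removal (zero-phase FIR high-pass,
`y[n] = Σ b_i x[n−i]` applied forward and backward) and ICA-based artifact
rejection, each channel's spectral power

    SP = Σ_k |X_k|²,   X_k = Σ_n x_n e^(−j2πkn/N)

is summed within theta (4–7 Hz), alpha (8–15 Hz), beta (16–31 Hz) and
gamma (32–45 Hz), giving a 40 × 56 feature matrix (20 subjects × 2
conditions; 14 channels × 4 bands). Per feature, a two-group one-way ANOVA
is tested against the Bonferroni level 0.05/14 ≈ 0.00357, and discrimination
is scored by sensitivity, specificity and accuracy

    Se = TP/(TP+FN),  Sp = TN/(TN+FP),  Acc = (TP+TN)/(TP+FP+TN+FN)

under 10 × 10-fold stratified cross-validation with Youden-optimal ROC
thresholds chosen on the training folds. Significant theta/alpha features
are standardized, reduced by PCA to 95% cumulative variance, and
classified by a Gini-impurity decision tree whose nodes stop splitting
when pure or smaller than 20% of all observations.

## Worked example

A complete run on a synthetic cohort (shortened to 16 s trials so it
finishes in seconds; drop `duration_s` for the full 2-minute design):

```r
library(phraseeg)
library(dplyr)

cfg <- pipeline_config(synth_config(duration_s = 16), base_seed = 42)
res <- run_pipeline(cfg, "phraseeg_out")

res$report
#> <classifier_report> 10 x 10-fold CV (fully nested)
#>   retained components: 4-5 (median 5)
#>   global accuracy: 89.75% (Se 89.50%, Sp 90.00%)
#>   confusion (rows = truth, normalized):
#>      predicted
#> truth     I    II
#>    I  0.900 0.100
#>    II 0.105 0.895

res$stats |> filter(band == "theta") |>
  select(channel, rho, se_pct, sp_pct, acc_pct, significant)
#> # A tibble: 14 × 6
#>    channel          rho se_pct sp_pct acc_pct significant
#>  1 AF3     0.0924         50     90      70   FALSE
#>  3 F3      0.0000285      94     75      84.5 TRUE
#>  5 T7      0.0000000706   86     89      87.5 TRUE
#>  8 O2      0.000724       70     90      80   TRUE
#>  9 P8      0.000124       85.5   95      90.2 TRUE
#> 12 F4      0.0000290      80     86      83   TRUE
#>  # … remaining channels not significant
```

Reading the output: the generator plants a +50% amplitude boost (so
(1.5)² ≈ 2.25× power) in the theta and alpha bands of channels F3, F4,
P8, O2 and T7 in condition II. Exactly those five channels come out
significant under the 0.00357 threshold (`rho` is the ANOVA p-value), with
single-feature cross-validated accuracies of 80–90%; the combined
PCA + tree classifier reaches 89.75% with a near-symmetric confusion
matrix. `run_pipeline()` also writes `features.csv`, one
`stats_<band>.csv` table per band (14 channel rows each, mirroring the
per-band results-table layout), `report.json`, `topo.json` and `run.log`
to the output directory, and re-running with the same `base_seed`
reproduces every file bit for bit.

Individual stages are exported too — `generate_cohort()`,
`preprocess_recording()`, `build_feature_matrix()`, `channel_stats()`,
`evaluate_feature_cv()`, `cross_validated_classify()`,
`summarize_topography()` — along with `autoplot()` methods for topographic
maps and confusion matrices, and broom-style `tidy()` / `glance()` for the
classifier report. A thin command-line wrapper lives at
`inst/scripts/eeg-pipeline.R`.

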