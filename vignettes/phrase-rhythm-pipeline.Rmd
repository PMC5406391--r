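---
title: "Band-power analysis of EEG responses to musical phrase structure: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power analysis of EEG responses to musical phrase structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phraseeg)
```

## The problem

A listening study contrasts two musical phrase structures — a rondo-form
movement (condition I) against a bipartite sonata movement (condition II) —
and asks whether scalp EEG distinguishes them. Each of 20 subjects listens
to both 2-minute pieces while a 14-channel consumer headset (AF3, F7, F3,
FC5, T7, P7, O1, O2, P8, T8, FC6, F4, F8, AF4 of the 10–20 system) records
at 128 Hz. The analysis chain is:

1. **Preprocess** — remove baseline drift with a zero-phase FIR high-pass,
   reject non-neural sources by ICA, optionally cancel referenced noise
   with an LMS adaptive filter, then band-limit to 4–45 Hz.
2. **Features** — per channel, a full-length FFT and the spectral power
   (sum of squared DFT magnitudes) in the canonical bands theta (4–7 Hz),
   alpha (8–15 Hz), beta (16–31 Hz), gamma (32–45 Hz): a 40 × 56 matrix
   (subject × condition rows; channel × band columns).
3. **Statistics** — per feature: Shapiro–Wilk and Levene diagnostics, a
   two-group one-way ANOVA, significance under the Bonferroni-corrected
   level 0.05/14 ≈ 0.00357, and a single-feature discrimination score from
   10 × 10-fold stratified cross-validation with ROC-optimal thresholds.
4. **Classifier** — Bonferroni-significant theta/alpha features,
   standardized, reduced by PCA to 95% cumulative variance, classified by
   a Gini decision tree whose nodes stop splitting when pure or smaller
   than 20% of all observations, all evaluated by the same repeated
   stratified CV.

The original recordings are not publicly available, so the package ships a
seeded synthetic cohort generator with the statistical structure the
analysis assumes; every stage is tested against it.

## The synthetic cohort generator

Each channel $c$ of a recording is

$$x_c[n] = g_s\,\varepsilon_{r,c} \sum_{b} A_{c,b}\, o_{b,c}[n]
          \;+\; \text{pink}[n] \;+\; \text{artifacts}[n],$$

* $o_{b,c}$ — independent unit-variance Gaussian noise band-limited to
  band $b$ (white noise through an ideal band-pass whose cosine taper is
  folded *inside* the band, so spectral energy is exactly confined;
  rescaled to variance 1). Band-limited noise, not sinusoids, keeps the
  FFT stage honest: energy spreads over all in-band bins rather than
  collapsing into one.
* $A_{c,b}$ — per-band amplitudes (defaults 4, 3, 2, 1 signal units for
  theta–gamma, falling off with frequency like real EEG), multiplied by
  $1 + \delta$ when the recording is condition II, $c$ is an effect
  channel and $b$ an effect band. Band *power* therefore scales by
  $(1+\delta)^2$. Defaults: effect channels {F3, F4, P8, O2, T7}, effect
  bands {theta, alpha} — the channels and bands the study reports as most
  responsive.
* $g_s$ — a per-subject lognormal gain (sd 0.1 on the log scale), shared
  by both of a subject's recordings; $\varepsilon_{r,c}$ — a
  per-recording, per-channel lognormal jitter (sd 0.2) representing
  electrode-contact and impedance variability, which on consumer saline
  headsets differs markedly between channels and re-seatings. The split
  matters: the subject gain is common noise that no feature combination
  can cancel, while the channel jitter averages out across channels —
  this is what lets a multi-channel classifier outperform the information
  available to any single feature.
* pink — a 1/f background (amplitude sd 2) from spectrally shaped white
  noise.
* artifacts — Hann-windowed blink bumps (~0.3 s, default 0.25 /s,
  amplitude 30) on the four frontal channels only; electrode-pop step
  discontinuities (default 0.02 /s, amplitude 25) on one random channel
  each; a common-phase 50 Hz mains sinusoid (amplitude 1). Each recording
  carries its artifact ground truth as an attribute so removal stages can
  be tested against it.

Every random draw derives from a single integer seed, per subject,
condition, channel and band, so identical configurations reproduce
byte-identical cohorts, and a subject's gain survives across conditions.

The default effect size is $\delta = 0.5$. It was calibrated once, at full
study scale, so that the cross-validated classifier accuracy lands in the
mid-80s-percent regime the method is expected to reach on well-separated
cohorts ($\delta = 0.45$ gave ~80%, $\delta = 0.5$ gave 87–89% over the
calibration seeds); it also coincides with the effect size used by the
recovery suite.

What the generator does **not** emulate: musical structure or
event-related potentials, phase coupling or any cross-channel correlation
beyond the shared gains, non-stationarity within a trial, or realistic
artifact morphology beyond the three stylized families. Passing tests on
this cohort therefore demonstrate that the *pipeline machinery* behaves as
specified — estimator conventions, error control, CV hygiene — not that
the scientific effect exists in real listeners.

## Preprocessing choices

* **Baseline removal** is a 0.5 Hz high-pass, order 512, applied
  forward/backward. The high-pass is built by spectral inversion of a
  unit-DC-gain windowed-sinc low-pass, so the DC coefficient sum is
  exactly zero; after filtering, each channel is explicitly demeaned
  (the passband itself carries a small finite-sample mean). 0.5 Hz is the
  conventional EEG drift cutoff; the order shrinks automatically on short
  recordings so the reflection padding (3 × (order + 1) samples,
  odd-symmetric so offsets and drifts do not create edge steps) fits.
* **Zero phase** comes from the forward/backward pass: phase responses
  cancel, the magnitude response squares, and a passband sinusoid's
  cross-correlation with its filtered self peaks at lag 0 (tested).
* **ICA** is a seeded FastICA: whitening by eigendecomposition, symmetric
  fixed-point iteration with the logcosh contrast, sources ordered by
  kurtosis, signs fixed by positive skewness. The neural part of the
  synthetic model is Gaussian, so source directions inside that subspace
  are not identifiable — which is irrelevant for artifact rejection, since
  flagging targets the identifiable non-Gaussian components.
* **Artifact flags**, with thresholds exposed as arguments: kurtosis > 5
  (impulsive sources); > 60% of source power below 4 Hz *and* squared
  mixing weights concentrated (> 50%) on AF3/AF4/F7/F8 (blink
  topography); > 50% of power within 50 ± 1 Hz (mains). The thresholds
  are conventional orders of magnitude, not fitted to anything; the
  false-flag rate on artifact-free cohorts is tested to stay ≤ 10%.
* **Band-limiting to 4–45 Hz happens after component removal.** Whether
  it should precede or follow ICA is genuinely open; removing components
  first lets the blink rule see the sub-4 Hz power it keys on. The stage
  order is configurable.
* The **LMS canceller** (8 taps, normalized step) is off by default: it
  needs a noise reference, which real deployments rarely log. Against the
  generator's known 50 Hz track it removes ≥ 90% of line power (tested).
* Bad-channel interpolation is deliberately absent: with 14 widely spaced
  channels there is no defensible neighbourhood to interpolate from.

## Feature conventions

One rectangular-window FFT over the full recording, no Welch averaging and
no epoching — the spectral power statistic is a plain sum of squared DFT
magnitudes, and averaging schemes would change it. The spectrum is
one-sided; Parseval's identity under this convention
($\sum_k w_k |X_k|^2 = N \sum_n x_n^2$, with $w_k = 1$ at DC and Nyquist,
2 elsewhere) is enforced to $10^{-6}$ relative in the tests. Band sums
include both edges; on a 128 Hz grid the canonical band edges never
collide, so no bin is counted twice. Powers are absolute, not normalized —
the downstream standardization step handles scale — and multiplying a
recording by $k$ multiplies every feature by exactly $k^2$ (tested).

## Statistics

The ANOVA always runs; Shapiro–Wilk and Levene p-values are reported
alongside rather than gating it (a constant group reports `NA`, read as
"not normal"). For two groups the F statistic is the squared pooled t
(tested to $10^{-10}$). The Bonferroni divisor is 14 — the number of
channels, matching the study's own correction — with `n_comparisons`
available for the stricter 56-way version.

"Maximizing ROC performance" is implemented as Youden's
$J = Se + Sp - 1$. Candidate thresholds sit at midpoints between adjacent
distinct training scores (plus infinite sentinels), both class-assignment
directions are evaluated and the one with larger AUC kept, and ties break
toward higher specificity, then the lower threshold. With all scores tied
the curve degenerates to the sentinels ($J = 0$) and is flagged. Note one
consequence of the direction rule: the *retained* AUC is the folded
statistic $\max(A, 1-A)$, whose null expectation is above 0.5; chance-level
behaviour is asserted on the fixed-direction area.

Cross-validation is stratified 10-fold, repeated 10 times; per-iteration
confusion counts give Se/Sp/Acc, averaged over the 100 iterations and
reported as percentages to two decimals. With 20 + 20 rows every fold
holds exactly 2 of each class.

## Classifier

Selection (theta/alpha features at $p \le 0.05/14$, falling back to all
theta/alpha if none passes), per-column standardization, PCA, and the tree
are all refit inside each training fold by default — the pooled
alternative (`paper_mode = TRUE`) fits selection and PCA once on all data
and cross-validates only the tree. The pooled protocol leaks the held-out
rows' covariance into the components and is optimistic by a few points on
synthetic cohorts; both are provided because the original description is
ambiguous about which was used, and neither is asserted as "the" protocol.

Features are standardized before PCA because band powers span orders of
magnitude (theta amplitudes are 4× gamma by default); unstandardized PCA
would load almost entirely on low-frequency columns. Components are
retained until cumulative explained variance reaches 95%, taking the
smallest such count.

The tree maximizes the weighted Gini impurity decrease over all
(component, midpoint-threshold) candidates; a node becomes a leaf when
pure, when smaller than $\lceil 0.2\,N \rceil$ samples ($\lceil \cdot \rceil$
so that "less than 20%" is literal), or when no split improves impurity.
Ties break toward the lowest component index, then the lowest threshold;
leaf labels are the majority class, ties going to condition I. Midpoint
thresholds and deterministic tie-breaks make refits bit-reproducible.

### Single features versus the combined classifier

On the published tables the combined PCA + tree accuracy exceeds the best
single feature by over 15 points. The synthetic cohorts reproduce the
*direction* of the machinery (the combined classifier exploits
cross-channel structure a single feature cannot) but not a 15-point gap,
and the package's tests do not assert one. The reason is instructive: the
published per-feature p-values (down to ~$10^{-16}$, i.e. |t| ≈ 13 at
n = 40) mathematically imply near-perfect single-feature separability,
which contradicts the published single-feature accuracies of 60–69%. No
coherent generative model can match both numbers at once, so the package
reports the two quantities side by side and leaves their comparison to
the data at hand.

## Problem sizes and numerical tolerances

The test and acceptance suites run the full study design (20 subjects × 2
conditions × 14 channels) while shortening recordings: 120-sample
(~0.94 s) recordings for the ANOVA null-level suite (level does not depend
on band-power estimator precision), 8 s recordings for the
effect-recovery suite (at 0.94 s the theta band spans only 3 Fourier bins
and estimator noise, ~58% relative sd, would mask the effect; 8 s
restores ~18%), and 4 s recordings for the classifier suites. These sizes
are the package's chosen operating points for its own validation;
full-scale (120 s) runs are exercised by the geometry check, the
calibration, and `scripts/acceptance.R`.

Key tolerances: Parseval to $10^{-6}$ relative (achieved ~$10^{-13}$);
ICA reconstruction to $10^{-6}$ relative Frobenius; PCA orthonormality to
$10^{-8}$; F = t² to $10^{-10}$; filter passband ripple 1–2%; Monte-Carlo
rate checks carry explicit sampling-error slack.

## Known limitations

* EDF support is a minimal single-record writer/reader (16-bit, ASCII
  header) sufficient for round-tripping the package's own files; it is not
  a general EDF(+) implementation.
* The LMS stage requires an explicit noise reference; no reference
  estimation is attempted.
* ICA determinism is per seed; across BLAS implementations small numeric
  differences can reorder near-degenerate (Gaussian-subspace) components.
* The generator's condition effect is multiplicative and stationary;
  none of the temporal structure of music listening is modelled.
* Alternative classifiers (LDA, QDA, logistic regression, SVM, k-NN) are
  out of scope; the tree is the model of record.
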