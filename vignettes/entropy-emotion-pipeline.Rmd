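---
title: "Entropy features, electrode selection and emotion classification from short EEG windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy features, electrode selection and emotion classification from short EEG windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegentropy)
```

## The problem and the pipeline

`eegentropy` implements a complete affective-computing pipeline for
recognizing three emotional states (negative, neutral, positive) from short
windows of multichannel EEG. The design mirrors a common wearable-device
protocol: eight electrodes (two frontal, AF3/AF4, and six temporal,
FT7/FT8/T7/T8/TP7/TP8) sampled at 256 Hz, with each subject-session
consisting of 30 trials of 50 s (10 trials per emotion label). Recordings
of this kind are rarely shareable, so the package ships a synthetic-EEG
generator that emulates the session structure end to end; every downstream
stage (filtering, segmentation, feature extraction, electrode selection,
classification, evaluation) is exercised against it.

The stages are:

1. **Band-pass filtering** at 1--50 Hz (zero-phase Butterworth).
2. **Segmentation** into 0.5 s windows (128 samples) with 50% overlap.
   One 50 s trial yields `floor((12800 - 128)/64) + 1 = 199` windows per
   channel; a full session yields 5,970 windows per channel and
   30 × 8 × 199 = 47,760 window-channel segments.
3. **Entropy features**: one scalar per window per channel, using one of
   six measures (below), min--max normalized to [0, 1] per channel within a
   subject.
4. **Electrode selection**: per channel, a one-way ANOVA over the three
   label groups followed by Tukey HSD pairwise contrasts; an electrode is
   adopted only when all three pairwise adjusted p-values are ≤ 0.05
   (inclusive threshold).
5. **Classification**: a one-vs-rest RBF-kernel SVM on the adopted
   channels, and an MLP and a 1-D CNN on all eight channels.
6. **Evaluation**: stratified 5-fold cross-validation (subject-dependent)
   and leave-one-subject-out (LOSO, subject-independent), reported as
   accuracy, per-class sensitivity/specificity from the one-vs-rest
   confusion counts, and per-class ROC AUC.

## The entropy measures

All six measures quantify irregularity of a 128-sample window; all use the
natural logarithm and are reported normalized to [0, 1] by the log of the
number of states. Hyperparameters are standard community defaults sized to
the window length, exposed in `entropy_config()`:

| Measure | Definition | Defaults |
|---|---|---|
| PEE | Shannon entropy of ordinal (rank) pattern frequencies | m = 3, τ = 1, / log 3! |
| SVE | Shannon entropy of normalized singular values of the delay embedding | m = 3, τ = 1, / log 3 |
| APE | Pincus Φ_m − Φ_{m+1}, self-inclusive Chebyshev matching | m = 2, r = 0.2·SD |
| SAE | Richman–Moorman −log(A/B), self-matches excluded | m = 2, r = 0.2·SD |
| SPE | Shannon entropy of the normalized power spectrum (positive bins, DC excluded) | FFT estimator (Welch switchable) |
| CWE | Shannon entropy of per-scale Morlet CWT energies | 32 log-spaced scales over 1–50 Hz |

Numerical details that matter:

* **Ordinal ties** (PEE) break by order of occurrence, a stable rule that
  matters on quantized windows.
* **Tolerance floor**: the APE/SAE tolerance is floored at
  `1e-12 · max(1, |mean(x)|)` so constant windows are well defined (both
  measures return 0 there). A sample-entropy window with matches at length
  m but none at m + 1 returns `Inf` and is propagated as a missing value,
  never as an arbitrary large number.
* **SVD entropy** mean-centers the window before embedding, so the measure
  reflects fluctuation structure and is invariant to a baseline offset,
  like the other five.
* **Morlet parameter**: the CWT uses an L1-normalized analytic Morlet with
  center-frequency parameter ω₀ = 10. With 32 log-spaced scales over
  1–50 Hz the grid spacing is 0.126 in log-frequency; ω₀ = 10 makes the
  wavelet's log-frequency selectivity (≈ 1/ω₀) about half a grid step, so
  a pure tone concentrates its energy on roughly two adjacent scales and
  narrowband signals score distinctly lower than broadband noise. The
  classical ω₀ = 6 leaves a tone smeared over four scales, which halves
  the usable dynamic range of the measure on this grid.
* The CWT is computed by frequency-domain (circular) convolution; on
  128-sample windows the lowest-frequency scales extend beyond the window
  and wrap. This is consistent across windows and therefore harmless for a
  relative complexity feature, but absolute low-frequency energies should
  not be over-interpreted.
* APE/SAE inner loops are compiled (Rcpp); the test suite checks every
  optimized path against naive direct-definition oracles to 1e-10.

## What the synthetic generator emulates

`generate_session()` builds each trial as

> coherent rhythm oscillation + ρ · pink noise,

scaled to a common amplitude (default 20 µV SD, a typical scalp EEG
magnitude). The oscillation is one sinusoid per canonical band — delta,
theta, alpha, beta, gamma at 2, 6, 10, 20, 36 Hz with relative amplitudes
0.25, 0.25, 1.5, 0.1, 0.06 (alpha-dominant, as in relaxed scalp EEG) — with
phases drawn once per subject and channel. The noise is 1/f (pink),
synthesized with a deterministic amplitude spectrum and random phases.
The emotion-class effect is the **noise-to-oscillation ratio ρ**: on the
configured informative channels (default `T8`) ρ follows
`class_complexity[label]`; everywhere else all labels share `base_ratio`.

Three generator design choices deserve explanation:

* **Irregularity, not amplitude, carries the class.** All six entropy
  measures are (by construction or through the relative tolerance)
  amplitude-invariant, so an amplitude effect would be invisible to the
  features. ρ directly sets the regular-to-irregular balance that entropy
  measures respond to, monotonically: the suite verifies a Spearman rank
  correlation ≥ 0.9 between ρ and each measure's mean over 100 windows
  across five ρ levels spanning 0.05–1. Approximate entropy is the reason
  that sweep is capped at ρ = 1: its well-known small-sample bias makes it
  *decline* again on heavily noise-dominated 128-sample windows (the
  defect sample entropy was designed to remove), so its monotone range is
  the oscillation-to-balanced regime.
* **Deterministic spectra, random phases.** Both the rhythm phases (fixed
  per subject-channel) and the pink noise (fixed amplitude spectrum) are
  chosen so that window statistics carry *no trial-level random effect* on
  null channels. The electrode-selection ANOVA treats windows as
  independent observations — as the analysis it implements does — and
  per-trial spectral fluctuations would silently inflate its false-adoption
  rate. With this construction the trial-factor F on null channels is ≈ 1
  and the per-electrode false-adoption rate stays within its nominal
  bounds.
* **Class-complexity levels.** The default map (0.2, 0.6, 1.0) produces a
  moderate, strictly ordered effect. `strong_class_effect()` =
  (0.05, 0.5, 5) — log-spaced over two orders of magnitude, from
  oscillation-dominated to noise-dominated — is the preset used for
  parameter-recovery demonstrations, where the question is whether the
  pipeline recovers a *clearly present* effect, not whether it can detect a
  marginal one.

Per-subject heterogeneity multiplies amplitude and ρ by
`exp(N(0, σ²))` offsets (σ = 0.15 by default; 0.35 in the
"heterogeneous subjects" LOSO experiments). Because features are min–max
normalized per subject, amplitude offsets wash out and the ρ offset is what
makes cross-subject generalization genuinely harder than within-subject
evaluation.

**What the generator does not emulate**: ocular/muscle/line artifacts,
electrode drift and impedance changes, volume-conduction correlation
between channels, non-stationarity within trials, or realistic spatial
topographies. Passing tests therefore demonstrate that the pipeline's
machinery is correct and recovers known effects under clean conditions —
not that comparable accuracies would be reached on real recordings.

Window overlap has one subtle consequence worth knowing: adjacent windows
share half their samples, so with trial-level label assignment a
cross-validation split at the window level is slightly optimistic even
under the null (we measure ≈ 34–37% where chance is 33.3%). This mirrors
the evaluation design it reproduces; a trial-blocked split would remove it.

## Electrode selection

`select_electrodes()` runs `aov()` + `TukeyHSD()` per channel and applies
the inclusive rule *adopt ⇔ max(pairwise p) ≤ α* (α = 0.05). Decisions are
monotone in the p-values, degenerate inputs are defined (identical groups
give p = 1; zero within-group variance with distinct means gives the
clipped floor), and p-values are clipped to [1e-16, 1]. Because windows
within a trial are autocorrelated, the test's independence assumption is
approximate; this is documented rather than corrected, matching the
analysis being reproduced. Selection is always per subject × measure;
`selection_frequency()` aggregates adoption counts across decisions, and
the packaged worked examples (`example_selection_pvalues()`,
`example_selection_survey()`) reproduce the published adopt/reject column
and the T8-most-adopted ranking.

## Classifiers

* **SVM**: libsvm (e1071) machines wrapped in an explicit one-vs-rest
  reduction (one binary machine per emotion), so each class has a
  continuous decision score for ROC analysis. C = 1;
  γ = 1/(n_features · var(X)).
* **MLP**: input → dense(128, ReLU) → softmax(3).
* **1D-CNN**: the 8-value feature vector treated as a length-8 sequence →
  conv1d(256 filters, kernel 3, same padding, stride 1, no pooling) →
  flatten → dense(128, ReLU) → dense(128, ReLU) → softmax(3). Kernel 3 and
  no pooling are the natural choices for an 8-step sequence.
* Both networks train with Adam (lr 0.001), categorical cross-entropy,
  batch 64, up to 100 epochs with early stopping (patience 10) on a
  stratified 10% validation split, all seeded and exactly reproducible.
  The networks are implemented directly with matrix arithmetic inside the
  package — at 8 input features per segment this is fully adequate and
  keeps the dependency surface small.

Nonlinear embeddings (t-SNE/UMAP) are deliberately *not* reimplemented:
`embed_features()` defines a pluggable backend contract
(`register_embedding_backend()`), raises a clear error when no backend is
registered, and `pca_project()` provides the from-scratch linear baseline
(eigendecomposition of the covariance matrix).

## Evaluation schemes and expected ordering

`crossval_5fold()` (stratified, seeded) models the subject-dependent
setting; `loso()` trains one pooled model per held-out subject for the
subject-independent setting. On heterogeneous synthetic subjects the mean
LOSO accuracy should not exceed the mean 5-fold accuracy — the acceptance
suite verifies this ordering as a mean over 10 seeded campaigns (single
seeds can go either way when the subject effect is small relative to the
class effect).

Specificity is computed as TN/(TN+FP), the standard definition, alongside
sensitivity TP/(TP+FN) and per-class one-vs-rest accuracy
(TP+TN)/(TP+TN+FP+FN).

## Problem sizes used in the checks

The automated checks run at the following scales, chosen to exercise the
full session arithmetic where it matters and reduced trial durations where
only statistical behavior is being verified: segmentation and the
SAE + 1D-CNN subject-dependent run use one full session (30 × 50 s,
5,970 × 8 features); electrode-selection recovery uses 20 full sessions
(one per seed); the chance-level and LOSO-ordering experiments use 10 s
trials (39 windows per trial-channel), 4 subjects and 10 seeds for the
ordering; oracle equivalence uses 200 random series of length ≤ 64.
Networks in the checks train for 15–20 epochs with early stopping; the
package default remains 100.

## Known limitations

* ANOVA on overlapping windows is anti-conservative in principle; the
  generator is built so the null is exchangeable, but on real data the
  within-trial autocorrelation caveat stands.
* Approximate entropy is reported as defined (including its bias); use
  sample entropy when monotone complexity response over a wide range
  matters.
* The EDF writer targets the subset of EDF+C needed here (one data record
  per trial, one annotations signal carrying the trial label); it is not a
  general-purpose EDF library.
* Printed p-values in the packaged worked example are floored at 0.001 by
  their source, so reproduction is asserted at the verdict level, not on
  raw p equality.
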