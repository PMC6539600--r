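---
title: "Methods: SDH texture features for tremor-severity grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SDH texture features for tremor-severity grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorsdh)
```

## The problem and the signal model

Parkinsonian action tremor is an involuntary oscillation, typically in the
4–6 Hz band, superimposed on voluntary hand motion. The acquisition protocol
this package targets records one hand at a time with a leap-motion
controller at 40 samples/s for 15 s while the patient holds the hand still
for 10 s and then pushes a virtual ball ~100 mm along the lateral (x) axis.
Each recording is 600 samples of 40 channels (position and velocity triplets
for five fingertips and the palm centre, plus the hand-rotation quaternion);
the analysis tracks a single channel, the palm-centre lateral position
`Cp(x)`.

The modelling idea is that tremor severity is a *texture* property of the
position series: how a sample relates to its immediate neighbour. The
sum-and-difference-of-histograms (SDH) technique, classical for 2D images,
transfers directly to 1D. With quantized levels `V(l)` and displacement
`M = 1`,

* `VD(l) = V(l) - V(l-M)` collects per-sample displacements,
* `VS(l) = V(l) + V(l-M)` collects local position pairs,

and within a sliding window of size `N` the normalized histograms
`ĥS, ĥD` (counts divided by `N`) summarize the local texture. Nine scalar
features are computed per window, following the standard SDH estimates: with
`μ = ½ Σ_j j ĥS(j)`,

| feature | formula |
|---|---|
| mean | `μ` |
| variance | `½ (Σ_j (j−2μ)² ĥS + Σ_k k² ĥD)` |
| energy | `(Σ_j ĥS²)(Σ_k ĥD²)` |
| correlation | `½ (Σ_j (j−2μ)² ĥS − Σ_k k² ĥD)` |
| entropy | `−Σ_j ĥS log ĥS − Σ_k ĥD log ĥD` |
| contrast | `Σ_k k² ĥD` |
| homogeneity | `Σ_k ĥD/(1+|k|)` |
| cluster shade | `Σ_j (j−2μ)³ ĥS` |
| cluster prominence | `Σ_j (j−2μ)⁴ ĥS` |

These formulas imply the identity `contrast = variance − correlation`, which
the test suite asserts on every window, and for a pure sinusoid of amplitude
`A` and frequency `f` sampled at `fs`, the difference vector is itself a
sinusoid of amplitude `2A sin(πf/fs)`, so contrast (in squared quantization
units times `bin_width²`) approaches `2A² sin²(πf/fs)` for windows spanning
many periods — the closed-form check used in the tests.

Contrast grows, and homogeneity falls, monotonically with oscillation
amplitude at fixed frequency; that is the mechanism by which two scalars per
window suffice to grade severity levels 0/1/2.

## Tunable parameters

* `M` (displacement, samples): 1. Larger lags are supported but unswept;
  at 40 sps a lag of 1 sample maximizes sensitivity to 4–6 Hz oscillations.
* `N` (window size, sum/difference samples): the main resolution/accuracy
  trade-off. The sweep grid is the 250 odd sizes 3–501; the focal report
  uses 149, 299, 449 (the quartiles of that range).
* `stride` (window step, samples): 1 by default — maximal overlap, the
  largest possible number of labelled windows per recording.
* `bin_width` (quantization, mm): 0.1 by default, matching the tracker's
  sub-millimetre accuracy; the SDH formalism needs integer levels and the
  acquisition device does not dictate a grid. Offset is the per-recording
  minimum, which makes all difference-histogram features invariant to a
  constant position offset (asserted by test).
* homogeneity `kernel`: the printed weight `1/(1+l)` is undefined at
  `l = −1` once difference values are signed; the package defaults to the
  magnitude reading `1/(1+|l|)` and exposes the classical `1/(1+l²)` as an
  option. Both keep weights in (0, 1]; no claim is made about which the
  original analysis used.
* entropy log base: natural. The base only rescales the feature and is
  recorded for reproducibility.
* classifiers: bagged trees (30 unpruned trees on bootstrap replicates of
  the training set, bootstrap size = train size, every feature available at
  every split, majority vote) and k-nearest-neighbour with Euclidean
  distance, `k = 1` ("fine" KNN). Neither hyperparameter set is published;
  these are the common defaults for those presets.

## The synthetic cohort: what it does and does not emulate

No patient data is distributed, so the package simulates recordings that
reproduce the protocol's *structure*: 600 samples at 40 sps; a 10 s hold
then a smoothstep push of 100 mm whose sign follows the hand; an additive
sinusoidal tremor with per-recording frequency uniform in 4–6 Hz and random
phase; Gaussian sensor noise (sd 0.05 mm); fingertip channels as rigid
offsets from the palm; velocities as sampled first differences; an identity
rotation quaternion. The default cohort composition is the published one:
39 retained recordings (levels 22/14/3 across both hands, with the
gender split), plus the one level-3 right hand that the bookkeeping
excludes.

Amplitude is the free parameter — the study reports no amplitude statistics
for its patients. The defaults (0.2 / 1.5 / 4.0 mm for levels 0/1/2) were
fixed once, before any evaluation, on two grounds: level 0 must be dominated
by physiological motion of the same order as sensor noise and the 0.1 mm
quantization, and levels must be ordered with 0 and 1 closest together,
since clinically those two are the hard pair. Tremor is injected on the
lateral axis only, which is what gives the coordinate-selection experiment
a ground truth: `Cp(x)` must outperform `Cp(z)`.

What the simulator does **not** model: re-emergent tremor latency, amplitude
fluctuation over the recording, frequency drift, tracking dropouts, gender
or age effects, or kinetic-vs-postural differences between the hold and push
phases. Consequently, a pipeline that classifies the synthetic cohort
perfectly is shown to be *correctly wired and sensitive to band-limited
amplitude differences* — not to be a validated clinical grader. Tests
passing here say nothing about accuracy on real patients.

## Evaluation protocol and the leakage question

The reference protocol combines both hands' windows, balances the three
classes by random undersampling, splits 70/30 at the window level, and
repeats 30 times, reporting min/mean/max of accuracy and one-vs-rest
precision, sensitivity and specificity. `repeat_evaluation()` implements
exactly that and is what `window_sweep()` uses by default.

Window-level splitting, however, places near-duplicate overlapping windows
of the same recording on both sides of the split. On the synthetic cohort
this saturates accuracy for *any* channel with recording-specific structure
— even one carrying no tremor information. For the two experiments whose
purpose is a *comparison of information content* (which coordinate, which
feature), the package therefore defaults to the leakage-safe recording-level
split, where all windows of a recording stay on one side; the window-level
behaviour remains available via `grouping = "window"`. `window_sweep()`
keeps the window-level default because it mirrors the reference metric
protocol; its absolute numbers should be read with the leakage caveat in
mind. Whether the original analysis respected patient identity in its split
is not stated; both behaviours are provided and neither is asserted as the
original one.

A related bookkeeping note: with only three level-2 recordings of 600
samples, at most `3 × (600 − N)` level-2 windows exist at stride 1, so a
balanced draw of 1800 windows per class is not reachable from the default
39-recording cohort at any window size. The balancing check in the tests
and the acceptance script therefore uses a 10-recordings-per-level synthetic
composition, where 1800 per class is available at `N = 399`.

## Numerical and degenerate-input choices

* Histograms store only non-zero masses; `0·log 0` never arises and each
  window's masses sum to 1 exactly (counts/N), asserted to 1e-12.
* Undefined metric ratios (0/0, e.g. sensitivity of a class absent from a
  test side) are reported as `NaN`, never coerced to 0.
* A class unseen in training still occupies a zero row/column of the
  confusion matrix, so counts are conserved.
* Seeds: every grid cell and repetition derives its seed from the master
  seed and the cell's identity via a stable string hash, so sub-grids
  reproduce the full grid's cells bit for bit.
* Recordings shorter than `N + M` samples are skipped with a warning during
  dataset assembly, and error when asked for directly.
* An empty recording file, a renamed channel, or a non-numeric cell are hard
  errors naming the offending channel or data row.

## Problem sizes used in the checks

Unit tests run on 200-sample recordings (a 5 s variant of the protocol) and
six-recording cohorts; the acceptance-style checks use the full default
39-recording cohort with 10 repetitions per window size on the reduced grid
{9, 49, 149, 299, 449} and 2 repetitions for the coordinate comparison.
These sizes were chosen as the smallest at which the monotone window-size
trend and the coordinate ordering are stable across seeds.

## Known limitations

* The SDH feature extractor is the package's own; only its surrounding
  machinery (CSV I/O, bagged trees via `randomForest` with `mtry = p`, KNN
  via `class::knn`, plotting) delegates to established packages.
* Axis conventions of the tracker are assumed (x = lateral push direction),
  not asserted; recordings with a different frame should be remapped at
  import.
* Severity levels above 2 are excluded, not modelled.
* The quaternion channels are stored and round-tripped but never analysed.
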