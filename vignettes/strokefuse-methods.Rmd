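---
title: "Fusing lesion probability maps with rs-fMRI biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing lesion probability maps with rs-fMRI biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokefuse)
```

## The problem

T1-weighted segmentation models for white-matter infarcts transfer poorly
across scanners and cohorts: a model that performs well on its training
distribution can drop to a Dice overlap of 0.2-0.4 on an independent clinical
dataset. Resting-state fMRI probes a complementary physical quantity — local
BOLD signal dynamics — and lesioned white matter shows altered oscillatory
behaviour. `strokefuse` implements a pipeline that (1) screens a large
catalogue of time-series features for lesion-to-white-matter contrast,
(2) fuses the strongest features with the continuous output of a
segmentation model through a voxel-wise logistic model, and (3) asks whether
the selected biomarker carries prognostic information about recovery.

Because the clinical data this workflow targets are access-restricted, the
package ships a fully parameterised synthetic cohort generator and treats it
as a first-class component: every statistical claim the test suite makes is
made about data whose ground truth is known and planted.

## Pipeline overview

1. **Simulate** (`generate_cohort`): masks, probability maps, multi-run
   BOLD, assessment scores.
2. **Extract** (`extract_subject_maps`): build the ROI, slide a 3×3×3
   window, emit 85 features per valid voxel per run.
3. **Screen** (`rank_features`): modified Fisher score per feature per scan;
   rank by the mean over training scans.
4. **Fuse** (`grid_search_fit`): voxel-wise logistic model of probability
   map + top features, coefficients by coarse full-grid search on training
   Dice.
5. **Evaluate** (`evaluate_visit`): three contenders under a subject-level
   50/50 split and its swap; paired t-tests on test Dice.
6. **Correlate** (`run_families`): two Holm-controlled families of
   recovery regressions, plus the between-visit amplitude decline test.

## The feature catalogue

Each valid window yields 85 named features: 77 automated signal-processing
metrics in seven groups, plus 8 literature rs-fMRI features
(`feature_registry()` is the canonical list). The automated groups are
populated with standard definitions:

* **Raw signal (19)** — mean, RMS, SD, moment skewness, non-excess
  kurtosis, peak (max absolute), min/median/max, type-7 quartiles and IQR,
  crest/impulse/clearance/shape factors, and SNR/SINAD/THD in dB.
* **Power spectrum (3)** — single-taper periodogram of the mean-removed
  series, no zero padding (at ~123 samples, segment averaging would cost
  too much resolution): peak amplitude over 0 < f ≤ Nyquist, its frequency,
  total power.
* **Signal envelope (13) and envelope spectrum (3)** — statistics of the
  analytic-signal magnitude envelope of the *mean-removed* series. Removing
  the mean first matters: BOLD series carry a large baseline offset, and
  the envelope of `offset + a(t)` collapses to the series itself, making
  every envelope feature a duplicate of its raw counterpart.
* **Autoregressive (9) and detrended + AR (10)** — Burg fits of order 1-8,
  order selected by minimum `AIC = T·ln(mean(e²)) + 2·(order+1)` on
  conditional one-step residuals; first coefficient, dominant-pole frequency
  (and, in the detrended group, its damping ratio), residual MSE/MAE and
  moments. "First frequency" is implemented as the dominant-pole frequency;
  the alternative reading (spectral peak of the AR transfer function) is
  close for the dominant pole and was not also emitted to keep the registry
  at its fixed size.
* **Linearly de-trended (20)** — the raw-signal statistics recomputed after
  removing the least-squares line, plus the de-trended signal power. The
  source catalogue's twentieth entry in this group is ambiguous (its printed
  table repeats a name); signal power was chosen as the one distinct,
  standard statistic missing from the group.
* **Literature (8)** — band amplitudes of fluctuation and band power ratios
  for 0.01-0.04, 0.04-0.08 and 0.08-0.10 Hz (bins assigned half-open,
  `[low, high)`, with the top band closed), Kendall's W across the window's
  voxel series, and the mean pairwise Kendall tau-b. Both concordance
  variants are emitted because the classical regional-homogeneity statistic
  is W over a neighbourhood but pairwise tau is the natural two-series
  analogue.

Numerical conventions: constant or degenerate windows return 0 for any
statistic whose denominator vanishes (and such features are excluded from
Fisher ranking), so degenerate windows cannot dominate the screening stage.
SNR/SINAD/THD floor their component powers at a relative 1e-15 so pure
tones give large finite dB values rather than infinities. Spectral peak
frequency of an all-zero series is reported as the lowest bin.

The concordance features are the only super-linear per-window cost and are
implemented in compiled code (bit-packed order indicators; exact
tie-corrected fallback); everything else is vectorised across all windows
of a run.

## ROI and sliding window

The analysis ROI is the union of the white-matter and lesion masks, 2×
downsampled (a coarse voxel is in-ROI iff at least half of its 2×2×2
children are; an "any child" rule is available). Runs discard their first 5
frames. Every ROI voxel collects the in-ROI members of its 3×3×3
neighbourhood; windows with fewer than 2 members are invalid — a purely
geometric rule. The window's mean series feeds the univariate features; the
individual member series feed the concordance features. The choice of
mean-series aggregation is isolated behind `sliding_window_maps` so the
per-voxel alternative can be swapped in.

## Screening

The modified Fisher score of a feature map is
`(Mean_lesion − Mean_WM)² / SD_WM²` — the squared contrast normalised by
white-matter variance alone (not the classical two-class criterion, which
sums both variances). It is computed per scan; ranking uses the mean over
every training scan with equal weight per scan, ties broken by registry
order. The score is invariant under positive affine transforms of the map,
so ranking raw or z-scored maps is equivalent.

## Fusion model

At each ROI voxel, infarct log-odds are modelled as
`β₀ + β₁·z(probmap) + Σ βⱼ·z(featureⱼ)`, with every input z-scored per
subject within the ROI. Feature z-maps are zero-clipped in the direction of
their training contrast: positive-contrast features zero `z < 0.1`,
negative-contrast features zero `z > −0.1`. (The literal text this rule
derives from — "z < 0.1 or −0.1 < z" — zeroes nearly everything if read
verbatim; the directional reading is implemented and the clause is exposed
in one function, `zero_clip`, so the alternative is one edit away.)

Coefficients come from a coarse full-grid search: 3 offset levels
{−2, 0, 2}, 4 probability-map levels {0.5, 1, 2, 4}, and 6 levels
{0, 0.25, 0.5, 1, 2, 4} per feature — 432 combinations with two features.
The level values are this package's choice (only the level counts are fixed
by the protocol); they span decision-threshold shifts from permissive to
conservative, and zero is included for each feature so the multivariate
grid nests the univariate model. The winning combination maximises mean
training Dice (prediction = probability > 0.5, equivalently linear
predictor > 0); ties go to the smallest-norm coefficients, then enumeration
order. Gradient-based and simplex optimisers are deliberately absent.

Three contenders are compared: the original probability map thresholded at
0.5; the re-optimised model (grid search over offset and map weight only);
and the multivariate model with the top-k (k ≤ 2) features. The
multivariate model is fitted and scored on run-aggregated feature maps
(mean of per-run z-maps — the least-assumptive pooling); applying the
fitted model to each run's maps individually yields the across-run SD
reported next to each subject's Dice. Scoring on the aggregate rather than
per run keeps the training and evaluation regimes identical; at seven runs
the aggregate is also the better-estimated map.

## Evaluation protocol

Subjects are split 50/50 at the subject level (the training half takes the
extra subject when the count is odd); repeated scans of one subject never
cross the split. The swap of the split is evaluated as well, so each
subject is tested exactly once across the pair, and the two test means are
averaged for final reporting. The paired t-test between contenders pairs
per-subject test Dice values; pairing on subjects matches the layout in
which such results are tabulated.

## Outcome statistics

The per-subject biomarker scalar is the mean Fisher score of the selected
feature over a visit's runs. Two families of simple regressions are tested:
the prognostic family (assessment change on subacute amplitude) and the
longitudinal-change family (assessment change on amplitude change). Each
family of three tests — FIM Walk, word comprehension, Posner reaction time
— is controlled at FWER 0.05 with Holm's step-down thresholds
`α/(m−i+1)` = {0.0167, 0.025, 0.05}. The subacute-versus-chronic amplitude
decline is a paired t-test on the per-subject summaries.

## The synthetic cohort

What the generator plants, per subject:

* **Geometry** — a ball-like white-matter compartment with a smoothly
  irregular boundary on the native grid (an early thin-annulus variant made
  boundary windows systematically smaller in one compartment, confounding
  every variance-like feature, and could not host lesions at realistic
  volume fractions; the thick compartment fixes both). The lesion is a
  randomly oriented ellipsoid of 100-200 native voxels (~5-15% of the
  compartment, matching the volume fraction scale of real infarct cohorts),
  placed fully inside.
* **BOLD** — on the 2×-downsampled grid: a spatially *coherent* oscillatory
  background (one random phase per spectral bin per run, flat-to-weak 1/f
  amplitude profile `0.2·(0.01/f)^0.05`), voxel-independent Gaussian noise
  whose SD varies over space through a smooth lognormal field
  (heteroscedastic physiological noise), an optional slow multiplicative
  amplitude drift of the background (`bg_modulation`, off by default — it
  models non-stationarity but occasionally produces extreme
  signal-to-noise-ratio outliers in small compartments), a baseline offset
  of 100, and 5 junk lead-in frames. Lesion voxels carry the same background with the
  amplitude of one subject-specific bin (drawn among the 0.01-0.10 Hz
  bins of the post-discard frequency grid) multiplied by the visit's
  planted contrast. Coherence is what makes the planted ratio survive
  window averaging exactly; with independent phases, averaging 27 voxels
  attenuates a planted tone below the maximum of the background bins and
  no spectral feature can recover it.
* **Contrasts** — subacute 2.5, chronic 1.5 (lesion/WM amplitude ratio at
  the injected bin), each jittered per subject on the log scale (SD 0.25).
  The decline mirrors the subacute-to-chronic biomarker attenuation the
  workflow is meant to detect; the absolute levels are set high enough that
  screening and fusion recover the plant reliably at desk-scale cohort
  sizes, which makes the resulting Fisher scores larger than those seen in
  vivo.
* **Probability map** — the lesion mask blurred (σ = 1.2 voxels), with
  probability 0.6 multiplied by a smoothed half-space ramp that suppresses
  60-95% of one side of the lesion (structural misses that no threshold
  can undo), plus sparse false-positive blobs and voxel noise, then scaled
  by an attenuation calibrated by bisection so that thresholding at 0.5
  reproduces a target Dice on the analysis grid. Targets are drawn
  right-skewed (Beta(0.7, 1.3) over [0, 0.85]): many near-misses, fewer
  good maps, the shape observed when a segmentation model is evaluated out
  of distribution.
* **Assessments** — word-comprehension change = 0.9 × planted subacute
  contrast + noise sized for a population R² of 0.42; FIM Walk change =
  −0.76 × contrast change + noise sized for R² 0.33 (clamped to the 1-7
  ordinal range but kept continuous so the noiseless planted line is exact);
  Posner change is pure noise. 14 of 20 subjects complete the chronic
  visit.

What the generator does **not** emulate: spatial autocorrelation of the
noise, head motion, registration error, partial-volume effects at tissue
boundaries, non-lesion pathology, and any realistic relationship between
T1-w appearance and the probability map. Passing tests on this cohort
demonstrate that the pipeline's statistics recover what was planted under
its assumptions — not that the biomarker works in vivo.

## Problem sizes and determinism

The package's own validation runs 20-subject cohorts on 16³ native grids
(8³ analysis grids, ~140 ROI voxels), 7 runs of 128 frames per visit —
small enough that a full screening-fusion-evaluation replicate takes ~25 s
on one core, so distributional claims can be checked over 20 seeded
replicates. Every random stage derives its seed deterministically from the
cohort seed and subject index: the same configuration reproduces the same
cohort byte for byte, and `run_all` writes a provenance log (package
version, seeds, config hash) next to its outputs.

## Known limitations

* The 77 automated metrics use this package's frozen standard definitions;
  no attempt is made to reproduce any commercial toolbox bit-for-bit.
* The fusion grid levels are package defaults, configurable per analysis;
  conclusions about specific coefficient values should not be compared
  across different level sets.
* With two near-collinear selected features (common, since the top features
  all track the planted tone), the grid search resolves the redundancy by
  its tie rule rather than by any shrinkage argument.
* Fisher scores from windows of heterogeneous size (ROI boundary) are
  noisier than interior ones; no size correction is applied beyond the
  minimum-cluster rule.
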