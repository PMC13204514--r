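# strokefuse

Screening resting-state fMRI time-series features for white-matter infarct
contrast, and fusing the strongest biomarkers with a segmentation model's
lesion probability map.

## What problem this solves

Deep-learning infarct segmentation models trained on one T1-weighted dataset
often degrade badly on an independent cohort. Resting-state BOLD dynamics
carry complementary, physiology-driven lesion contrast. This package is for
neuroimaging methods researchers who want a tested, fully reproducible
implementation of that fusion workflow:

* extract **85 features** per voxel from BOLD time series with a 3×3×3
  sliding window (77 automated signal-processing metrics — distribution
  shape, spectral, envelope, autoregressive, de-trended variants — plus 8
  literature features: band amplitudes of fluctuation, band power ratios,
  Kendall W and mean pairwise Kendall tau);
* rank them by the **modified Fisher score**

  $$\mathrm{Score}_i = \frac{(\mathrm{Mean}_{lesion} - \mathrm{Mean}_{WM})^2}{\mathrm{SD}_{WM}^2},$$

  computed per scan and averaged over training scans;
* fuse the top features with the probability map through a **voxel-wise
  logistic model**

  $$\ln\frac{p}{1-p} = \beta_0 + \beta_1\,z(\mathrm{probmap}) + \sum_j \beta_j\, z(\mathrm{fMRI}_j),$$

  with coefficients chosen by a coarse full-grid search (3×4×6×6 = 432
  combinations for two features) maximising mean training Dice,
  $\mathrm{Dice} = 2TP / (2TP + FP + FN)$;
* evaluate three contenders (original thresholded map, re-optimised map,
  multivariate fusion) under a **subject-level 50/50 split and its swap**,
  with paired t-tests on test Dice;
* test biomarker-recovery associations in two **Holm–Bonferroni controlled
  families** of simple regressions.

Because the clinical data such workflows target are access-restricted, the
package includes a seeded synthetic stroke-cohort generator (masks,
degraded probability maps, multi-run BOLD with a planted narrow-band
lesion oscillation, longitudinal assessment scores) as a first-class,
tested component. All claims in the test suite are made against planted
ground truth.

## Worked example

Simulate a small cohort, extract feature maps for the subacute visit,
screen, fuse and evaluate:

```r
library(strokefuse)

cfg    <- cohort_config(seed = 7)   # defaults: 20 subjects, 7 runs x 128 frames
cohort <- generate_cohort(cfg)

extracts <- lapply(cohort$subjects, extract_subject_maps,
                   visit = "subacute", config = cfg)
names(extracts) <- subject_ids(cohort)

ranking <- rank_features(cohort_fisher_tables(extracts))
head(as.data.frame(ranking), 3)
#>         feature mean_score sign rank
#> 1 spec_peak_amp       4.76    1    1
#> 2      dt_sinad       4.47    1    2
#> 3     raw_sinad       4.41    1    3

ev <- evaluate_visit(extracts, seed = 1, k = 2)
ev$report
#>          model mean_original mean_swapped mean_dice
#> 1 multivariate         0.752        0.781     0.766
#> 2     original         0.182        0.500     0.341
#> 3  reoptimized         0.633        0.683     0.658
round(unlist(ev$t_multi_vs_reopt[c("t", "p", "mean_diff")]), 4)
#>         t         p mean_diff
#>    2.6939    0.0144    0.1085
```

The spectral peak amplitude — the maximum of a window's amplitude spectrum
below the 0.25 Hz Nyquist limit — tops the ranking because the generator
plants a narrow-band oscillation in lesion voxels. Fusing it with the
degraded probability map lifts mean test Dice from 0.66 (re-optimised
threshold) to 0.77, a paired-t significant gain (p = 0.014 over the 20
subjects, each tested once across the two splits); the original
0.5-threshold map sits at 0.34. Numbers are from this configuration and
seed and vary with both.

The recovery analyses follow the same pattern at the cohort level:

```r
amp    <- amplitude_summary(extracts)            # mean Fisher score per subject
assess <- generate_assessments(cohort)           # planted word-comprehension effect
fam    <- run_families(data.frame(subject_id = amp$subject_id,
                                  subacute = amp$amplitude, chronic = NA),
                       assess, families = "prognostic")
fam$prognostic[, c("dependent", "slope", "p", "r2", "flagged")]
#>            dependent slope       p   r2 flagged
#> 1           fim_walk  0.14 0.12408 0.19   FALSE
#> 2 word_comprehension  0.29 0.00021 0.70    TRUE
#> 3          posner_ms -4.07 0.20829 0.13   FALSE
```

Only the planted word-comprehension association survives the
Holm-controlled prognostic family.

`run_all()` drives the whole pipeline (simulate → extract → screen → fit →
evaluate → correlate) from one config list or YAML file and writes every
table plus a provenance log; `inst/scripts/strokefuse` wraps it for shell
use.

See `vignettes/strokefuse-methods.Rmd` for the models, parameter choices
and the generator's assumptions.

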