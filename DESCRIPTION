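Package: strokefuse
Title: White-Matter Infarct Detection by Fusing Lesion Probability Maps
    with Resting-State fMRI Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens 85 resting-state fMRI time-series features (77 automated
    signal-processing metrics plus 8 literature features such as band-limited
    amplitude of fluctuation and Kendall concordance) for lesion-to-white-matter
    contrast with a modified Fisher score, and fuses the strongest biomarkers
    with a segmentation-model lesion probability map through a voxel-wise
    logistic model fitted by coarse full-grid search on training Dice overlap.
    Includes a seeded synthetic stroke-cohort generator (masks, probability
    maps, multi-run BOLD, longitudinal assessment scores), subject-level
    split-and-swap evaluation of three contender models, and Holm-Bonferroni
    controlled recovery-correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
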