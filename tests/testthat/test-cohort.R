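# Synthetic cohort generator: determinism, structural invariants, planted
# effects and on-disk round-trip.

test_that("generation is deterministic for a fixed config and seed", {
  cfg <- tiny_config()
  s1 <- generate_subject(cfg, 1, visits = "subacute")
  s2 <- generate_subject(cfg, 1, visits = "subacute")
  expect_identical(s1$lesion_mask, s2$lesion_mask)
  expect_identical(s1$probmap, s2$probmap)
  expect_identical(s1$bold_runs, s2$bold_runs)
  expect_identical(s1$contrasts, s2$contrasts)
  # different subjects differ
  s3 <- generate_subject(cfg, 2, visits = "subacute")
  expect_false(identical(s1$lesion_mask, s3$lesion_mask) &&
                 identical(s1$bold_runs, s3$bold_runs))
})

test_that("masks and probability map satisfy the structural invariants", {
  cfg <- tiny_config(seed = 21)
  for (i in 1:3) {
    s <- generate_subject(cfg, i, visits = "subacute")
    expect_true(all(s$wm_mask %in% c(0L, 1L)))
    expect_true(all(s$lesion_mask %in% c(0L, 1L)))
    expect_equal(sum(s$wm_mask * s$lesion_mask), 0) # disjoint compartments
    expect_gte(sum(s$lesion_mask), cfg$lesion_volume_range[1] * 0.5)
    expect_true(all(s$probmap >= 0 & s$probmap <= 1))
    roi_native <- (s$wm_mask | s$lesion_mask)
    expect_true(all(s$probmap[!roi_native] == 0)) # masked outside ROI
    expect_gte(sum(downsample_mask(s$lesion_mask)), 2)
  }
})

test_that("volumes within the requested range are placed, absurd ones error", {
  cfg <- tiny_config()
  cfg$lesion_volume_range <- c(3000, 3000) # cannot fit in a 16^3 compartment
  expect_error(generate_subject(cfg, 1, visits = "subacute"),
               "white-matter compartment")
})

test_that("the planted spectral contrast is exactly recoverable without noise", {
  # all nuisance processes off: white noise and the slow background drift
  cfg <- tiny_config(noise_sd = 0, bg_modulation = 0, n_frames = 64)
  s <- generate_subject(cfg, 1, visits = c("subacute", "chronic"))
  lesion_ds <- downsample_mask(s$lesion_mask)
  roi_ds <- build_roi(s$wm_mask, s$lesion_mask)
  wm_idx <- which(roi_ds == 1 & lesion_ds == 0)
  les_idx <- which(lesion_ds == 1)
  for (visit in c("subacute", "chronic")) {
    bold <- discard_frames(s$bold_runs[[visit]][[1]], cfg$n_discard_frames)
    nt <- dim(bold)[4]
    V <- matrix(bold, prod(dim(bold)[1:3]), nt)
    amp_at <- function(idx) {
      x <- colMeans(matrix(V[idx, ], length(idx)))
      mean(vapply(idx, function(v)
        oracle_dft(V[v, ], cfg$tr_seconds)$amp[s$injected_bin], numeric(1)))
    }
    ratio <- amp_at(les_idx) / amp_at(wm_idx)
    expect_equal(ratio, unname(s$contrasts[visit]), tolerance = 0.1)
  }
  # equal planted contrasts make the two visits exchangeable up to noise:
  # with no noise the planted lesion amplitude is identical across visits
  cfg2 <- tiny_config(noise_sd = 0, bg_modulation = 0, n_frames = 64,
                      contrast_jitter_sd = 0,
                      subacute_peak_contrast = 2,
                      chronic_peak_contrast = 1.9999999)
  s2 <- generate_subject(cfg2, 1, visits = c("subacute", "chronic"))
  expect_equal(unname(s2$contrasts["subacute"] / s2$contrasts["chronic"]),
               1, tolerance = 1e-5)
})

test_that("chronic contrast must lie below subacute contrast", {
  expect_error(tiny_config(subacute_peak_contrast = 1.5,
                           chronic_peak_contrast = 1.5),
               "smaller")
})

test_that("thresholded probability maps span the requested Dice range", {
  cfg <- cohort_config(n_subjects = 10, n_runs_per_visit = 1, n_frames = 16,
                       grid_shape = c(16, 16, 16),
                       probmap_quality_range = c(0, 0.85), seed = 33)
  res <- t(vapply(1:10, function(i) {
    s <- generate_subject(cfg, i, visits = "subacute")
    les <- downsample_mask(s$lesion_mask)
    c(achieved = dice_index(downsample_volume(s$probmap) > 0.5, les)$dice,
      target = s$probmap_target_dice)
  }, numeric(2)))
  # calibration tracks the target and the spread covers poor-to-good maps
  expect_lt(min(res[, "achieved"]), 0.2)
  expect_gt(max(res[, "achieved"]), 0.45)
  expect_lt(mean(abs(res[, "achieved"] - res[, "target"])), 0.15)
})

test_that("chronic completers get the chronic visit, others do not", {
  cfg <- cohort_config(n_subjects = 6, n_runs_per_visit = 1, n_frames = 16,
                       grid_shape = c(16, 16, 16),
                       n_chronic_completers = 4, seed = 5)
  cohort <- generate_cohort(cfg)
  has_chronic <- vapply(cohort$subjects,
                        function(s) "chronic" %in% s$visits, logical(1))
  expect_equal(sum(has_chronic), 4)
  expect_equal(which(has_chronic), cohort$completers)
})

test_that("assessments carry the planted effects", {
  cfg <- tiny_config(n_subjects = 6, n_chronic_completers = 6)
  cohort <- generate_cohort(cfg)
  # zero effect, zero noise: all word-comprehension changes are 0
  a0 <- generate_assessments(cohort, effect_slope = 0, noise_sd = 0,
                             fim_slope = 0, fim_noise_sd = 0)
  ch0 <- assessment_changes(a0)
  expect_true(all(abs(ch0$d_word) < 1e-12))
  # positive effect, zero noise: the downstream regression is a perfect line
  a1 <- generate_assessments(cohort, effect_slope = 2, noise_sd = 0)
  ch1 <- assessment_changes(a1)
  c_sub <- vapply(cohort$subjects, function(s) s$contrasts[["subacute"]],
                  numeric(1))
  fit <- suppressWarnings(simple_regression(c_sub, ch1$d_word))
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  # FIM stays in its ordinal range
  expect_true(all(a1$fim_walk >= 1 & a1$fim_walk <= 7))
})

test_that("the planted slope is recovered within 2 SE at n = 14", {
  # stub cohorts: assessments depend only on contrasts, so simulate those
  cfg <- cohort_config(n_subjects = 14, n_chronic_completers = 14, seed = 1)
  covered <- logical(400)
  set.seed(99)
  for (r in seq_along(covered)) {
    contrasts <- cfg$subacute_peak_contrast *
      exp(rnorm(14, 0, cfg$contrast_jitter_sd))
    chronics <- cfg$chronic_peak_contrast *
      exp(rnorm(14, 0, cfg$contrast_jitter_sd))
    stub <- structure(list(
      config = cfg,
      subjects = lapply(1:14, function(i) structure(list(
        subject_id = sprintf("sub-%02d", i),
        contrasts = c(subacute = contrasts[i], chronic = chronics[i]),
        visits = c("subacute", "chronic")), class = "subject_bundle")),
      completers = 1:14), class = "stroke_cohort")
    a <- generate_assessments(stub, effect_slope = 0.9, seed = r)
    ch <- assessment_changes(a)
    fit <- lm(ch$d_word ~ contrasts)
    se <- summary(fit)$coefficients[2, 2]
    covered[r] <- abs(coef(fit)[2] - 0.9) <= 2 * se
  }
  expect_gte(mean(covered), 0.9)
})

test_that("a cohort round-trips through disk losslessly", {
  cfg <- tiny_config(n_subjects = 2, n_chronic_completers = 2)
  cohort <- generate_cohort(cfg)
  assess <- generate_assessments(cohort)
  dir <- file.path(tempdir(), "cohort_rt")
  unlink(dir, recursive = TRUE)
  mf <- write_cohort(cohort, dir, assess)
  # manifest lists n_subjects x 2 visits x n_runs_per_visit BOLD files
  nbold <- sum(vapply(mf$subjects, function(e) length(unlist(e$bold_files)),
                      integer(1)))
  expect_equal(nbold, 2 * 2 * cfg$n_runs_per_visit)
  back <- read_cohort(dir)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]; b <- back$subjects[[i]]
    expect_equal(as.numeric(s$wm_mask), as.numeric(b$wm_mask))
    expect_equal(as.numeric(s$lesion_mask), as.numeric(b$lesion_mask))
    expect_equal(as.numeric(s$probmap), as.numeric(b$probmap))
    for (v in s$visits)
      for (r in seq_along(s$bold_runs[[v]]))
        expect_equal(as.numeric(s$bold_runs[[v]][[r]]),
                     as.numeric(b$bold_runs[[v]][[r]]))
    expect_equal(unname(s$contrasts), unname(b$contrasts))
  }
  expect_equal(back$assessments$word_comprehension,
               assess$word_comprehension)
  expect_equal(back$completers, cohort$completers)
})
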