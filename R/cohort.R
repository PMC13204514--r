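# Synthetic stroke-cohort generator: masks, probability maps, multi-run BOLD
# and longitudinal assessment scores, all seeded and parameterised.

# run code under a temporary RNG seed, restoring global RNG state afterwards
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.subject_seed <- function(config, subject_index, salt = 0) {
  as.integer((config$seed * 48271 + subject_index * 16807 + salt * 69621) %%
               2147483629) + 1L
}

# separable Gaussian smoothing with zero-padded borders
.gauss1 <- function(a, kern, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- matrix(b, db[1])
  out <- matrix(0, nrow(m), ncol(m))
  r <- (length(kern) - 1) / 2
  for (j in -r:r) {
    src <- seq_len(db[1]) - j
    ok <- src >= 1 & src <= db[1]
    out[ok, ] <- out[ok, ] + kern[j + r + 1] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, db), order(perm))
}

gauss_smooth3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  for (axis in 1:3) vol <- .gauss1(vol, kern, axis)
  vol
}

#' Configuration of a synthetic stroke cohort
#'
#' Defines the study conditions the generator emulates: 20 subjects with
#' seven BOLD runs per visit of 128 frames at TR = 2 s (five frames later
#' discarded), subacute and chronic visits with a planted narrow-band
#' oscillation in the lesion whose amplitude contrast declines from the
#' subacute to the chronic visit, an imperfect lesion probability map whose
#' baseline Dice spans a configurable range, and 14 of 20 subjects completing
#' the chronic follow-up.
#'
#' @param n_subjects number of subjects.
#' @param n_runs_per_visit BOLD runs per visit (>= 1).
#' @param n_frames frames per run before discard (> 5).
#' @param tr_seconds repetition time in seconds.
#' @param grid_shape native mask grid (the analysis ROI grid is this, 2x
#'   downsampled).
#' @param lesion_volume_range admissible lesion volume in native voxels.
#' @param subacute_peak_contrast planted lesion/WM amplitude ratio at the
#'   injected frequency for the subacute visit.
#' @param chronic_peak_contrast same for the chronic visit; must be smaller.
#' @param contrast_jitter_sd log-scale SD of the between-subject contrast
#'   spread (subjects differ in planted effect size).
#' @param probmap_quality_range interval of target baseline Dice (thresholded
#'   probability map vs lesion, on the analysis grid).
#' @param noise_sd white-noise SD of the BOLD background.
#' @param bg_amp,bg_exponent amplitude and 1/f exponent of the oscillatory
#'   BOLD background (`amp * (0.01 Hz / f)^exponent` per spectral bin).
#' @param bg_modulation depth of the slow multiplicative amplitude drift of
#'   the oscillatory background (physiological non-stationarity); 0 disables
#'   it.
#' @param probmap_smooth_sigma,probmap_noise_sd degradation-model knobs for
#'   the surrogate probability map (Gaussian blur in voxels; voxel noise SD).
#' @param n_chronic_completers subjects with a chronic visit (default: 70%,
#'   i.e. 14 of 20).
#' @param n_discard_frames leading frames discarded before analysis.
#' @param seed master RNG seed; identical config and seed reproduce the
#'   cohort exactly.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 20, n_runs_per_visit = 7,
                          n_frames = 128, tr_seconds = 2,
                          grid_shape = c(16, 16, 16),
                          lesion_volume_range = c(100, 200),
                          subacute_peak_contrast = 2.5,
                          chronic_peak_contrast = 1.5,
                          contrast_jitter_sd = 0.25,
                          probmap_quality_range = c(0, 0.85),
                          noise_sd = 0.5, bg_amp = 0.2, bg_exponent = 0.05,
                          bg_modulation = 0,
                          probmap_smooth_sigma = 1.2, probmap_noise_sd = 0.15,
                          n_chronic_completers = NULL,
                          n_discard_frames = 5, seed = 1) {
  if (is.null(n_chronic_completers))
    n_chronic_completers <- ceiling(0.7 * n_subjects)
  cfg <- list(n_subjects = n_subjects, n_runs_per_visit = n_runs_per_visit,
              n_frames = n_frames, tr_seconds = tr_seconds,
              grid_shape = grid_shape,
              lesion_volume_range = lesion_volume_range,
              subacute_peak_contrast = subacute_peak_contrast,
              chronic_peak_contrast = chronic_peak_contrast,
              contrast_jitter_sd = contrast_jitter_sd,
              probmap_quality_range = probmap_quality_range,
              noise_sd = noise_sd, bg_amp = bg_amp,
              bg_exponent = bg_exponent, bg_modulation = bg_modulation,
              probmap_smooth_sigma = probmap_smooth_sigma,
              probmap_noise_sd = probmap_noise_sd,
              n_chronic_completers = n_chronic_completers,
              n_discard_frames = n_discard_frames, seed = seed)
  stopifnot(n_subjects >= 1, n_runs_per_visit >= 1,
            n_frames > n_discard_frames, tr_seconds > 0,
            length(grid_shape) == 3, all(grid_shape >= 8),
            length(lesion_volume_range) == 2,
            lesion_volume_range[1] > 0,
            diff(lesion_volume_range) >= 0,
            probmap_quality_range[1] >= 0, probmap_quality_range[2] <= 1,
            noise_sd >= 0, n_chronic_completers <= n_subjects)
  if (chronic_peak_contrast >= subacute_peak_contrast)
    stop("chronic_peak_contrast must be smaller than subacute_peak_contrast")
  class(cfg) <- "cohort_config"
  cfg
}

# synthetic white-matter compartment on the native grid: a ball with a
# smoothly irregular boundary, sized so lesions at realistic WM volume
# fractions (~5-15%) fit fully inside
.wm_compartment <- function(grid_shape) {
  d <- grid_shape
  ctr <- (d + 1) / 2
  ax <- seq_len(d[1]) - ctr[1]
  ay <- seq_len(d[2]) - ctr[2]
  az <- seq_len(d[3]) - ctr[3]
  r <- sqrt(outer(outer(ax^2, ay^2, `+`), az^2, `+`))
  r_out <- 0.40 * min(d)
  bump <- gauss_smooth3d(array(stats::rnorm(prod(d)), d), 2)
  bump <- bump / max(stats::sd(bump), 1e-12)
  shell <- r <= r_out * (1 + 0.06 * bump)
  storage.mode(shell) <- "integer"
  shell
}

# random rotation matrix
.rand_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# voxelise an ellipsoid: centre (length 3), semi-axes a, rotation R
.ellipsoid_voxels <- function(centre, axes, R, grid_shape) {
  rmax <- ceiling(max(axes))
  lo <- pmax(floor(centre - rmax), 1)
  hi <- pmin(ceiling(centre + rmax), grid_shape)
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  u <- (g - matrix(centre, nrow(g), 3, byrow = TRUE)) %*% R
  inside <- (u[, 1] / axes[1])^2 + (u[, 2] / axes[2])^2 + (u[, 3] / axes[3])^2 <= 1
  g[inside, , drop = FALSE]
}

.place_lesion <- function(shell, config) {
  d <- dim(shell)
  cand <- which(shell == 1, arr.ind = TRUE)
  ctr0 <- (d + 1) / 2
  r_out <- 0.40 * min(d)
  rad <- sqrt(colSums((t(cand) - ctr0)^2))
  for (attempt in seq_len(300)) {
    v_target <- stats::runif(1, config$lesion_volume_range[1],
                             config$lesion_volume_range[2])
    r0 <- (3 * v_target / (4 * pi))^(1 / 3)
    u <- exp(stats::rnorm(3, 0, 0.2))
    axes <- r0 * u / prod(u)^(1 / 3)
    R <- .rand_rotation()
    # only try centres whose bounding sphere stays inside the outer boundary
    ok <- which(rad <= r_out - 0.95 * max(axes))
    if (length(ok) == 0) ok <- seq_len(nrow(cand))
    ctr <- cand[ok[sample.int(length(ok), 1)], ]
    vox <- .ellipsoid_voxels(ctr, axes, R, d)
    if (nrow(vox) < config$lesion_volume_range[1] * 0.5) next
    lin <- vox[, 1] + (vox[, 2] - 1) * d[1] + (vox[, 3] - 1) * d[1] * d[2]
    if (!all(shell[lin] == 1)) next
    lesion <- array(0L, d)
    lesion[lin] <- 1L
    if (sum(downsample_mask(lesion)) < 2) next # analysis grid needs >= 2 voxels
    return(lesion)
  }
  stop("lesion cannot be placed inside the white-matter compartment at the ",
       "requested volume range [", config$lesion_volume_range[1], ", ",
       config$lesion_volume_range[2], "] native voxels")
}

# surrogate probability map: blurred lesion * attenuation + structured noise,
# attenuation calibrated by bisection so the 0.5-thresholded map hits a target
# Dice on the analysis grid
.make_probmap <- function(lesion, roi_native, lesion_ds, config) {
  d <- dim(lesion)
  base <- gauss_smooth3d(lesion + 0, config$probmap_smooth_sigma)
  if (max(base) > 0) base <- base / max(base)
  # structural miss: with probability 0.6, suppress a random half-space of
  # the lesion so part of it is genuinely invisible to the probability map
  # (no threshold recovers it)
  if (stats::runif(1) < 0.6) {
    w <- stats::rnorm(3)
    w <- w / sqrt(sum(w^2))
    ctr <- colMeans(which(lesion == 1, arr.ind = TRUE))
    g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
    side <- array(as.numeric((g - matrix(ctr, nrow(g), 3, byrow = TRUE)) %*% w > 0), d)
    side <- gauss_smooth3d(side, 1)
    base <- base * (1 - stats::runif(1, 0.6, 0.95) * side)
  }
  bump <- gauss_smooth3d(array(stats::rnorm(prod(d)), d), 1.5)
  bump <- bump / max(stats::sd(bump), 1e-12)
  fp <- 0.6 * pmax(bump - 1.6, 0) # sparse false-positive blobs
  eps <- config$probmap_noise_sd * array(stats::rnorm(prod(d)), d)
  # target baseline Dice: right-skewed across subjects (many near-misses,
  # fewer good maps), matching the spread of out-of-distribution
  # segmentation-model performance
  qr <- config$probmap_quality_range
  target <- qr[1] + (qr[2] - qr[1]) * stats::rbeta(1, 0.7, 1.3)
  dice_at <- function(alpha) {
    p <- pmin(pmax(alpha * base + fp + eps, 0), 1) * (roi_native != 0)
    dice_index(downsample_volume(p) > 0.5, lesion_ds)$dice
  }
  lo <- 0; hi <- 4
  best_a <- 0; best_gap <- abs(dice_at(0) - target)
  for (i in seq_len(24)) {
    mid <- (lo + hi) / 2
    dm <- dice_at(mid)
    gap <- abs(dm - target)
    if (gap < best_gap) { best_gap <- gap; best_a <- mid }
    if (dm < target) lo <- mid else hi <- mid
  }
  p <- pmin(pmax(best_a * base + fp + eps, 0), 1) * (roi_native != 0)
  list(probmap = p, target_dice = target, attenuation = best_a)
}

# One BOLD run on the analysis grid. The oscillatory 1/f background is
# spatially coherent within the run (a global physiological signal with one
# random phase per spectral bin), white noise is voxel-independent, and
# lesion voxels carry the planted bin amplified by the visit contrast. The
# coherent background survives window averaging, so the planted
# lesion-to-WM amplitude ratio at the injected frequency is exact by
# construction; stabilisation lead-in frames are prepended.
.make_bold_run <- function(roi_ds, lesion_ds, k_planted, contrast, config) {
  nt <- config$n_frames - config$n_discard_frames
  K <- nt %/% 2
  d <- dim(roi_ds)
  roi_idx <- which(roi_ds != 0)
  les <- lesion_ds[roi_idx] != 0
  nv <- length(roi_idx)
  freq <- seq_len(K) / (nt * config$tr_seconds)
  prof <- config$bg_amp * (0.01 / freq)^config$bg_exponent

  phase <- stats::runif(K, 0, 2 * pi)
  synth <- function(amp) {
    S <- complex(length.out = nt)
    S[seq_len(K) + 1L] <- (nt / 2) * amp * exp(1i * phase)
    S[nt + 1L - seq_len(K)] <- Conj(S[seq_len(K) + 1L])
    Re(stats::fft(S, inverse = TRUE)) / nt
  }
  x_wm <- synth(prof)
  amp_les <- prof
  amp_les[k_planted] <- amp_les[k_planted] * contrast
  x_les <- synth(amp_les)

  # slow common amplitude drift of the oscillatory background: physiological
  # signals are non-stationary, so the signal envelope fluctuates with total
  # signal strength rather than with any single spectral line
  if (config$bg_modulation > 0) {
    km <- sample.int(3L, 1)
    g <- 1 + config$bg_modulation *
      cos(2 * pi * km * (0:(nt - 1)) / nt + stats::runif(1, 0, 2 * pi))
    x_wm <- x_wm * g
    x_les <- x_les * g
  }

  # heteroscedastic thermal/physiological noise: a smooth spatial gain field
  # modulates the white-noise SD so signal-to-noise quantities vary across
  # white matter the way they do in vivo
  eta <- gauss_smooth3d(array(stats::rnorm(prod(d)), d), 1.5)
  eta <- (eta - mean(eta)) / max(stats::sd(eta), 1e-12)
  sd_vox <- config$noise_sd * exp(0.6 * eta[roi_idx])

  full <- matrix(0, config$n_frames, nv)
  keep <- (config$n_discard_frames + 1):config$n_frames
  full[keep, !les] <- x_wm
  full[keep, les] <- x_les
  full[keep, ] <- full[keep, ] +
    matrix(stats::rnorm(nt * nv, 0, 1), nt, nv) *
      matrix(sd_vox, nt, nv, byrow = TRUE)
  full[-keep, ] <- matrix(stats::rnorm(config$n_discard_frames * nv, 0,
                                       2 * config$noise_sd + 0.5),
                          ncol = nv) +
    3 * exp(-seq_len(config$n_discard_frames))
  full <- full + 100

  V <- matrix(0, prod(d), config$n_frames)
  V[roi_idx, ] <- t(full)
  array(V, c(d, config$n_frames))
}

#' Generate one synthetic subject
#'
#' Places a connected ellipsoidal lesion inside the smoothed-annulus
#' white-matter compartment, builds a degraded surrogate probability map
#' calibrated to a target baseline Dice, and synthesises BOLD runs in which
#' lesion voxels carry a narrow-band oscillation (subject-specific frequency
#' in 0.01-0.10 Hz) whose amplitude exceeds the white-matter background by
#' the visit's planted contrast.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index (used for seeding).
#' @param visits visit labels to generate BOLD for.
#' @param seed RNG seed; defaults to a value derived from the config seed and
#'   subject index.
#' @return A `subject_bundle` list: masks and probability map on the native
#'   grid, BOLD runs per visit on the analysis grid, planted per-visit
#'   contrasts and the injected frequency.
#' @export
generate_subject <- function(config, subject_index,
                             visits = c("subacute", "chronic"),
                             seed = .subject_seed(config, subject_index)) {
  stopifnot(inherits(config, "cohort_config"),
            subject_index >= 1, subject_index <= config$n_subjects)
  visits <- match.arg(visits, c("subacute", "chronic"), several.ok = TRUE)
  .with_seed(seed, {
    shell <- .wm_compartment(config$grid_shape)
    lesion <- .place_lesion(shell, config)
    wm <- shell
    wm[lesion == 1] <- 0L
    roi_native <- (wm | lesion) + 0L
    lesion_ds <- downsample_mask(lesion)
    roi_ds <- build_roi(wm, lesion)
    pm <- .make_probmap(lesion, roi_native, lesion_ds, config)

    nt <- config$n_frames - config$n_discard_frames
    freq <- seq_len(nt %/% 2) / (nt * config$tr_seconds)
    k_ok <- which(freq >= 0.01 & freq <= 0.10)
    k_planted <- k_ok[sample.int(length(k_ok), 1)]

    contrasts <- c(
      subacute = config$subacute_peak_contrast *
        exp(stats::rnorm(1, 0, config$contrast_jitter_sd)),
      chronic = config$chronic_peak_contrast *
        exp(stats::rnorm(1, 0, config$contrast_jitter_sd)))

    bold_runs <- lapply(stats::setNames(visits, visits), function(v)
      lapply(seq_len(config$n_runs_per_visit), function(r)
        .make_bold_run(roi_ds, lesion_ds, k_planted, contrasts[[v]], config)))

    structure(list(subject_id = sprintf("sub-%02d", subject_index),
                   wm_mask = wm, lesion_mask = lesion, probmap = pm$probmap,
                   bold_runs = bold_runs, visits = visits,
                   contrasts = contrasts,
                   injected_freq_hz = freq[k_planted],
                   injected_bin = k_planted,
                   probmap_target_dice = pm$target_dice,
                   seed = seed),
              class = "subject_bundle")
  })
}

#' Generate a full synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return A `stroke_cohort`: the config, the list of subject bundles, and
#'   the indices of chronic-visit completers.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  completers <- .with_seed(.subject_seed(config, 0, salt = 1),
                           sort(sample.int(config$n_subjects,
                                           config$n_chronic_completers)))
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    generate_subject(config, i,
                     visits = if (i %in% completers)
                       c("subacute", "chronic") else "subacute"))
  structure(list(config = config, subjects = subjects,
                 completers = completers),
            class = "stroke_cohort")
}

#' Subject identifiers of a cohort
#' @param cohort a `stroke_cohort`.
#' @return Character vector of subject ids.
#' @export
subject_ids <- function(cohort) {
  vapply(cohort$subjects, `[[`, character(1), "subject_id")
}

#' Generate longitudinal assessment scores for a cohort
#'
#' Plants the recovery associations the outcome analyses look for: the change
#' in word comprehension is `effect_slope` times the subject's planted
#' subacute lesion contrast plus noise; the change in FIM Walk is
#' anti-correlated with the planted contrast change (`fim_slope` < 0); the
#' Posner cueing reaction-time change is independent noise. Only chronic
#' completers receive chronic-visit rows.
#'
#' Default noise levels are sized so the planted word-comprehension and FIM
#' associations have population R-squared of about 0.42 and 0.33 at the
#' generated contrast spread.
#'
#' @param cohort a `stroke_cohort`.
#' @param effect_slope word-comprehension points per unit planted contrast.
#' @param noise_sd SD of the word-comprehension change noise; `NULL` sizes it
#'   for R-squared 0.42 given the cohort's contrast spread.
#' @param fim_slope FIM Walk points per unit contrast change (negative).
#' @param fim_noise_sd SD of the FIM change noise; `NULL` sizes it for
#'   R-squared 0.33.
#' @param posner_sd SD (ms) of the Posner reaction-time change.
#' @param seed RNG seed.
#' @return Long data.frame with columns `subject_id`, `visit`, `fim_walk`,
#'   `word_comprehension`, `posner_ms`.
#' @export
generate_assessments <- function(cohort, effect_slope = 0.9, noise_sd = NULL,
                                 fim_slope = -0.76, fim_noise_sd = NULL,
                                 posner_sd = 40,
                                 seed = .subject_seed(cohort$config, 0, salt = 2)) {
  stopifnot(inherits(cohort, "stroke_cohort"))
  c_sub <- vapply(cohort$subjects, function(s) s$contrasts[["subacute"]],
                  numeric(1))
  c_chr <- vapply(cohort$subjects, function(s) s$contrasts[["chronic"]],
                  numeric(1))
  dc <- c_chr - c_sub
  n <- length(c_sub)
  sx <- max(stats::sd(c_sub), 1e-12)
  sdc <- max(stats::sd(dc), 1e-12)
  if (is.null(noise_sd))
    noise_sd <- if (effect_slope == 0) 1
      else abs(effect_slope) * sx * sqrt(0.58 / 0.42)
  if (is.null(fim_noise_sd))
    fim_noise_sd <- if (fim_slope == 0) 0.5
      else abs(fim_slope) * sdc * sqrt(0.67 / 0.33)

  .with_seed(seed, {
    word0 <- stats::rnorm(n, 25, 4)
    fim0 <- pmin(pmax(stats::rnorm(n, 4, 1), 1), 7)
    pos0 <- stats::rnorm(n, 450, 60)
    d_word <- effect_slope * c_sub + stats::rnorm(n, 0, noise_sd)
    d_fim <- fim_slope * dc + stats::rnorm(n, 0, fim_noise_sd)
    d_pos <- stats::rnorm(n, 0, posner_sd)

    ids <- subject_ids(cohort)
    sub <- data.frame(subject_id = ids, visit = "subacute",
                      fim_walk = fim0, word_comprehension = word0,
                      posner_ms = pos0, stringsAsFactors = FALSE)
    comp <- cohort$completers
    chr <- data.frame(subject_id = ids[comp], visit = "chronic",
                      fim_walk = pmin(pmax(fim0[comp] + d_fim[comp], 1), 7),
                      word_comprehension = word0[comp] + d_word[comp],
                      posner_ms = pos0[comp] + d_pos[comp],
                      stringsAsFactors = FALSE)
    rbind(sub, chr)
  })
}

#' Per-subject longitudinal assessment changes
#'
#' @param assessments table from [generate_assessments()] (or read back from
#'   CSV).
#' @return data.frame of completers with `d_fim`, `d_word`, `d_posner`
#'   (chronic minus subacute).
#' @export
assessment_changes <- function(assessments) {
  sub <- assessments[assessments$visit == "subacute", ]
  chr <- assessments[assessments$visit == "chronic", ]
  m <- match(chr$subject_id, sub$subject_id)
  data.frame(subject_id = chr$subject_id,
             d_fim = chr$fim_walk - sub$fim_walk[m],
             d_word = chr$word_comprehension - sub$word_comprehension[m],
             d_posner = chr$posner_ms - sub$posner_ms[m],
             stringsAsFactors = FALSE)
}
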