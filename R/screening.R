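# Modified-Fisher-score screening of feature maps for lesion-to-WM contrast.

#' Modified Fisher score of one feature map
#'
#' `Score = (Mean_Lesion - Mean_WM)^2 / SD_WM^2`, with the means and SD taken
#' over the valid voxels of the (downsampled) lesion mask and white-matter
#' mask respectively. The squared lesion-to-white-matter contrast is
#' normalised by the white-matter variance only.
#'
#' @param feature_map numeric 3D array (NA at invalid voxels) on the analysis
#'   grid.
#' @param lesion_mask,wm_mask binary 3D arrays on the same grid.
#' @return List with `score`, `mean_lesion`, `mean_wm`, `sd_wm`, `n_lesion`,
#'   `n_wm`.
#' @export
fisher_score <- function(feature_map, lesion_mask, wm_mask) {
  if (!identical(dim(feature_map), dim(lesion_mask)) ||
      !identical(dim(feature_map), dim(wm_mask)))
    stop("feature map and masks must share a grid")
  vl <- feature_map[lesion_mask != 0]
  vw <- feature_map[wm_mask != 0]
  vl <- vl[!is.na(vl)]
  vw <- vw[!is.na(vw)]
  if (length(vl) < 2 || length(vw) < 2)
    stop("need at least 2 valid voxels in each compartment")
  sw <- stats::sd(vw)
  if (sw == 0) stop("white-matter SD is zero; Fisher score undefined")
  ml <- mean(vl)
  mw <- mean(vw)
  list(score = (ml - mw)^2 / sw^2, mean_lesion = ml, mean_wm = mw,
       sd_wm = sw, n_lesion = length(vl), n_wm = length(vw))
}

#' Fisher scores of every feature in a feature-map set
#'
#' Vectorised version of [fisher_score()] over all 85 features of one scan.
#'
#' @param fms a `feature_map_set`.
#' @param lesion_mask,wm_mask binary 3D arrays on the analysis grid.
#' @return data.frame with one row per feature: `feature`, `score`,
#'   `mean_lesion`, `mean_wm`, `sd_wm`.
#' @export
fisher_scores_fms <- function(fms, lesion_mask, wm_mask) {
  stopifnot(inherits(fms, "feature_map_set"))
  if (!identical(fms$dim, dim(lesion_mask)) ||
      !identical(fms$dim, dim(wm_mask)))
    stop("feature-map set and masks must share a grid")
  les <- lesion_mask[fms$vox_idx] != 0
  wm <- wm_mask[fms$vox_idx] != 0
  if (sum(les) < 2 || sum(wm) < 2)
    stop("need at least 2 valid voxels in each compartment")
  ml <- colMeans(fms$values[les, , drop = FALSE])
  mw <- colMeans(fms$values[wm, , drop = FALSE])
  sw <- apply(fms$values[wm, , drop = FALSE], 2, stats::sd)
  data.frame(feature = fms$features,
             score = ifelse(sw > 0, (ml - mw)^2 / sw^2, NA_real_),
             mean_lesion = ml, mean_wm = mw, sd_wm = sw,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank features by mean Fisher score across training scans
#'
#' Averages the per-scan scores over every training run of every training
#' subject (equal weight per scan) and sorts in descending order of mean
#' score; ties are broken by registry order. Features with degenerate scores
#' on any scan (zero white-matter SD, sentinel-flagged) are excluded and
#' listed.
#'
#' @param per_run_scores list of per-scan score tables from
#'   [fisher_scores_fms()].
#' @return A `fisher_ranking` data.frame: `feature`, `mean_score`, `sign`
#'   (of the mean lesion-minus-WM contrast), `rank`; excluded features in
#'   `attr(, "excluded")`, the per-scan score matrix in `attr(, "scores")`.
#' @export
rank_features <- function(per_run_scores) {
  stopifnot(length(per_run_scores) >= 1)
  reg <- feature_names()
  smat <- vapply(per_run_scores, function(tb) tb$score[match(reg, tb$feature)],
                 numeric(length(reg)))
  smat <- matrix(smat, nrow = length(reg),
                 dimnames = list(reg, NULL))
  cmat <- vapply(per_run_scores,
                 function(tb) (tb$mean_lesion - tb$mean_wm)[match(reg, tb$feature)],
                 numeric(length(reg)))
  cmat <- matrix(cmat, nrow = length(reg))
  bad <- apply(smat, 1, function(x) any(!is.finite(x)))
  mean_score <- rowMeans(smat)
  contrast <- rowMeans(cmat)
  keep <- which(!bad)
  ord <- keep[order(-mean_score[keep], keep)] # registry order breaks ties
  out <- data.frame(feature = reg[ord], mean_score = mean_score[ord],
                    sign = ifelse(contrast[ord] >= 0, 1, -1),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- reg[bad]
  attr(out, "scores") <- smat
  class(out) <- c("fisher_ranking", "data.frame")
  out
}

#' Select the top-k ranked features
#'
#' @param ranking a `fisher_ranking`.
#' @param k number of features (<= number of ranked features).
#' @return data.frame with `feature`, `sign`, `mean_score` of the top k.
#' @export
select_top <- function(ranking, k) {
  stopifnot(inherits(ranking, "fisher_ranking"), k <= nrow(ranking))
  ranking[seq_len(k), c("feature", "sign", "mean_score")]
}

# ---- per-subject extraction orchestration ----------------------------------

#' Extract analysis-grid masks and per-run feature maps for one subject
#'
#' Builds the ROI (union of masks, 2x downsampled), discards stabilisation
#' frames, and runs the sliding window over every BOLD run of the requested
#' visit. The window geometry is computed once and shared across runs.
#'
#' @param subject a `subject_bundle`.
#' @param visit `"subacute"` or `"chronic"`.
#' @param config the `cohort_config` used to generate the subject.
#' @param max_order maximum AR order for the feature engine.
#' @return List with `fms_runs` (per-run `feature_map_set`s, raw values),
#'   `lesion_ds`, `wm_ds`, `roi_ds`, `probmap_ds`, `geometry`.
#' @export
extract_subject_maps <- function(subject, visit, config, max_order = 8) {
  stopifnot(inherits(subject, "subject_bundle"),
            visit %in% subject$visits)
  roi_ds <- build_roi(subject$wm_mask, subject$lesion_mask)
  lesion_ds <- downsample_mask(subject$lesion_mask)
  lesion_ds[roi_ds == 0] <- 0L
  wm_ds <- roi_ds
  wm_ds[lesion_ds != 0] <- 0L
  geom <- window_geometry(roi_ds)
  tr <- config$tr_seconds
  fms_runs <- lapply(seq_along(subject$bold_runs[[visit]]), function(r) {
    bold <- discard_frames(subject$bold_runs[[visit]][[r]],
                           config$n_discard_frames)
    sliding_window_maps(bold, roi_ds, tr = tr,
                        run_id = sprintf("%s_run-%d", visit, r),
                        geometry = geom, max_order = max_order)
  })
  list(subject_id = subject$subject_id, fms_runs = fms_runs,
       lesion_ds = lesion_ds, wm_ds = wm_ds, roi_ds = roi_ds,
       probmap_ds = downsample_volume(subject$probmap), geometry = geom)
}

#' Per-scan Fisher score tables for a set of extracted subjects
#'
#' @param extracts list of [extract_subject_maps()] results.
#' @return Flat list of per-scan score tables (input for [rank_features()]).
#' @export
cohort_fisher_tables <- function(extracts) {
  unlist(lapply(extracts, function(e)
    lapply(e$fms_runs, fisher_scores_fms, lesion_mask = e$lesion_ds,
           wm_mask = e$wm_ds)), recursive = FALSE)
}
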