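# Voxel-wise logistic fusion of the segmentation probability map with the
# selected rs-fMRI feature maps, optimised by coarse full-grid search on
# training Dice.

#' Dice overlap between two binary masks
#'
#' `2 * TP / (2 * TP + FP + FN)`. Two empty masks are defined as perfect
#' agreement (Dice 1) and flagged; an empty prediction against a non-empty
#' truth gives 0.
#'
#' @param prediction_mask,truth_mask binary arrays/vectors on the same grid.
#' @return A `dice_result` list with `tp`, `fp`, `fn`, `dice`, `both_empty`.
#' @export
#' @examples
#' dice_index(c(1, 1, 1, 0), c(1, 1, 0, 1))$dice # 2*2/(4+1+1)
dice_index <- function(prediction_mask, truth_mask) {
  if (!identical(dim(prediction_mask), dim(truth_mask)) ||
      length(prediction_mask) != length(truth_mask))
    stop("prediction and truth masks must share a grid")
  p <- prediction_mask != 0
  t <- truth_mask != 0
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  both_empty <- (tp + fp + fn) == 0
  dice <- if (both_empty) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, dice = dice,
                 both_empty = both_empty),
            class = "dice_result")
}

#' Zero out feature z-scores that oppose the training contrast
#'
#' For a positive-contrast feature, z-scores below 0.1 are zeroed; for a
#' negative-contrast feature, z-scores above -0.1 are zeroed. This stops a
#' feature from driving the infarct log-odds in the direction opposite to
#' its lesion-to-white-matter contrast.
#'
#' @param feature_zmap numeric vector or array of z-scores.
#' @param contrast_sign `+1`/`-1` (or `"+"`/`"-"`).
#' @return The clipped map.
#' @export
zero_clip <- function(feature_zmap, contrast_sign) {
  if (is.character(contrast_sign))
    contrast_sign <- if (contrast_sign == "-") -1 else 1
  if (contrast_sign >= 0) feature_zmap[feature_zmap < 0.1] <- 0
  else feature_zmap[feature_zmap > -0.1] <- 0
  feature_zmap
}

#' Coarse full-grid search levels
#'
#' Default levels: 3 for the offset, 4 for the probability-map weight, 6 for
#' each rs-fMRI feature weight; with two features this enumerates
#' 3 x 4 x 6 x 6 = 432 combinations.
#'
#' @param n_features number of rs-fMRI features (0, 1 or 2).
#' @param beta0,beta1,betaf level vectors for the offset, the probability-map
#'   coefficient, and each feature coefficient.
#' @return A list of per-parameter level vectors, class `fusion_grid`.
#' @export
fusion_grid <- function(n_features = 2, beta0 = c(-2, 0, 2),
                        beta1 = c(0.5, 1, 2, 4),
                        betaf = c(0, 0.25, 0.5, 1, 2, 4)) {
  stopifnot(n_features %in% 0:2)
  g <- c(list(beta0 = beta0, beta1 = beta1),
         if (n_features >= 1) rep(list(betaf), n_features))
  if (n_features >= 1)
    names(g)[3:(2 + n_features)] <- paste0("beta", seq_len(n_features) + 1)
  structure(g, class = "fusion_grid")
}

#' Number of combinations a grid enumerates
#' @param grid a [fusion_grid()].
#' @return Integer combination count (product of level cardinalities).
#' @export
grid_size <- function(grid) prod(vapply(grid, length, integer(1)))

#' Voxel-wise lesion probability under the fitted logistic model
#'
#' `p = 1 / (1 + exp(-(b0 + b1 * prob_z + sum_j b_j * feature_z_j)))`,
#' evaluated inside the ROI; voxels outside the ROI get probability 0.
#'
#' @param params a `fusion_params` object (or list with `beta0`, `beta1`,
#'   `beta_features`).
#' @param probmap_z z-scored probability map (vector or 3D array).
#' @param feature_zmaps list of z-scored (and zero-clipped) feature maps of
#'   the same shape.
#' @param roi_mask optional binary array; outside voxels are set to 0.
#' @return Probability volume/vector.
#' @export
logistic_probability <- function(params, probmap_z, feature_zmaps = list(),
                                 roi_mask = NULL) {
  for (f in feature_zmaps)
    if (!identical(dim(f), dim(probmap_z)) ||
        length(f) != length(probmap_z))
      stop("probability map and feature maps must share a grid")
  eta <- params$beta0 + params$beta1 * probmap_z
  bf <- params$beta_features
  for (j in seq_along(feature_zmaps)) eta <- eta + bf[j] * feature_zmaps[[j]]
  p <- stats::plogis(eta)
  if (!is.null(roi_mask)) {
    if (!identical(dim(roi_mask), dim(probmap_z)))
      stop("ROI mask grid mismatch")
    p[roi_mask == 0] <- 0
  }
  p
}

# per-subject fusion design: prob_z + clipped feature columns + truth at the
# valid window voxels
.design_matrix <- function(design, n_features) {
  nf_avail <- if (is.null(design$feats)) 0 else ncol(design$feats)
  if (n_features > nf_avail)
    stop("design provides ", nf_avail, " feature maps but ", n_features,
         " are requested")
  cbind(1, design$prob_z,
        if (n_features > 0) design$feats[, seq_len(n_features), drop = FALSE])
}

#' Fit fusion coefficients by coarse full-grid search
#'
#' Enumerates every coefficient combination of the grid; for each, binarises
#' the voxel-wise logistic probability at 0.5 (equivalently, linear predictor
#' above 0) for every training subject and averages the training Dice. The
#' combination with the highest mean training Dice wins; ties go to the
#' smallest-norm coefficients, then enumeration order.
#'
#' @param designs list of per-subject designs, each a list with `prob_z`
#'   (numeric vector), `feats` (matrix of clipped feature z-scores, may be
#'   `NULL`), and `truth` (logical vector).
#' @param grid a [fusion_grid()].
#' @param n_features number of rs-fMRI features used (0 = probability-map-only
#'   re-optimised model).
#' @return A `fusion_params` object: coefficients, the grid, the training
#'   mean Dice, and the full per-combination training report.
#' @export
grid_search_fit <- function(designs, grid = fusion_grid(n_features),
                            n_features = 2) {
  stopifnot(length(designs) >= 1)
  if (length(grid) == 0 || grid_size(grid) == 0) stop("empty grid")
  if (length(grid) != 2 + n_features)
    stop("grid has ", length(grid), " parameters; expected ", 2 + n_features)
  combos <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
  dice_mat <- matrix(0, nrow(combos), length(designs))
  for (s in seq_along(designs)) {
    X <- .design_matrix(designs[[s]], n_features)
    truth <- designs[[s]]$truth != 0
    L <- X %*% t(combos)
    pred <- L > 0
    tp <- colSums(pred & truth)
    fp <- colSums(pred & !truth)
    fn <- sum(truth) - tp
    denom <- 2 * tp + fp + fn
    dice_mat[, s] <- ifelse(denom == 0, 1, 2 * tp / denom)
  }
  mean_dice <- rowMeans(dice_mat)
  best <- which(mean_dice == max(mean_dice))
  if (length(best) > 1) {
    norms <- rowSums(combos[best, , drop = FALSE]^2)
    best <- best[norms == min(norms)]
  }
  best <- best[1]
  structure(list(beta0 = combos[best, 1], beta1 = combos[best, 2],
                 beta_features = if (n_features > 0)
                   combos[best, 3:(2 + n_features)] else numeric(0),
                 n_features = n_features, grid = grid,
                 train_mean_dice = mean_dice[best],
                 combo_index = best,
                 train_report = data.frame(combos, mean_dice = mean_dice)),
            class = "fusion_params")
}

#' Apply a fitted fusion model to one subject
#'
#' Computes the voxel-wise logistic probability, binarises at 0.5 and scores
#' the prediction against the truth.
#'
#' @param params a `fusion_params` object.
#' @param design a per-subject design as in [grid_search_fit()].
#' @return List with `prediction` (logical vector) and `dice` (a
#'   `dice_result`).
#' @export
apply_model <- function(params, design) {
  X <- .design_matrix(design, params$n_features)
  beta <- c(params$beta0, params$beta1, params$beta_features)
  pred <- as.vector(X %*% beta) > 0
  list(prediction = pred, dice = dice_index(pred, design$truth != 0))
}
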