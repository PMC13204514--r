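# ROI construction and sliding-window feature maps.

.pad_even <- function(x) {
  d <- dim(x)
  pd <- d + d %% 2
  if (all(pd == d)) return(x)
  out <- array(0, pd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

.fold2 <- function(x) {
  # sum over 2x2x2 children
  d <- dim(x)
  x <- x[seq(1, d[1], 2), , , drop = FALSE] + x[seq(2, d[1], 2), , , drop = FALSE]
  x <- x[, seq(1, d[2], 2), , drop = FALSE] + x[, seq(2, d[2], 2), , drop = FALSE]
  x[, , seq(1, d[3], 2), drop = FALSE] + x[, , seq(2, d[3], 2), drop = FALSE]
}

#' 2x spatial downsampling of a binary mask
#'
#' A coarse voxel is in-mask iff at least half (rule `"half"`, the default)
#' or at least one (rule `"any"`) of its 2x2x2 children are in-mask. Odd
#' dimensions are zero-padded before pooling.
#'
#' @param mask binary 3D array.
#' @param rule `"half"` or `"any"`.
#' @return Binary 3D array with halved (rounded-up) dimensions.
#' @export
downsample_mask <- function(mask, rule = c("half", "any")) {
  rule <- match.arg(rule)
  stopifnot(length(dim(mask)) == 3)
  cnt <- .fold2(.pad_even(mask != 0))
  out <- if (rule == "half") cnt >= 4 else cnt >= 1
  storage.mode(out) <- "integer"
  out
}

#' 2x mean-pooling of a continuous volume
#'
#' @param vol numeric 3D array.
#' @return 3D array of 2x2x2 block means.
#' @export
downsample_volume <- function(vol) {
  stopifnot(length(dim(vol)) == 3)
  .fold2(.pad_even(vol)) / 8
}

#' Build the analysis ROI from white-matter and lesion masks
#'
#' The ROI is the union of the two masks, 2x spatially downsampled to the
#' analysis grid.
#'
#' @param wm_mask,lesion_mask binary 3D arrays on the same (native) grid.
#' @param rule downsampling rule, see [downsample_mask()].
#' @return Binary 3D array on the downsampled grid.
#' @export
build_roi <- function(wm_mask, lesion_mask, rule = "half") {
  if (!identical(dim(wm_mask), dim(lesion_mask)))
    stop("white-matter and lesion masks must share a grid")
  downsample_mask((wm_mask != 0) | (lesion_mask != 0), rule = rule)
}

#' Discard initial scanner-stabilisation frames
#'
#' @param bold 4D array (x, y, z, t).
#' @param n number of leading frames to drop (default 5).
#' @return 4D array without the first `n` frames.
#' @export
discard_frames <- function(bold, n = 5) {
  stopifnot(length(dim(bold)) == 4, dim(bold)[4] > n)
  bold[, , , -seq_len(n), drop = FALSE]
}

#' Precompute sliding-window geometry for an ROI
#'
#' For every in-ROI voxel, collects the in-ROI members of its 3x3x3
#' neighbourhood; a window is valid iff it has at least 2 members (the
#' minimum cluster size rule). Validity is purely geometric.
#'
#' @param roi_mask binary 3D array.
#' @return A list with `dim`, `vox_idx` (linear indices of valid window
#'   centres), and `neighbors` (list of linear-index vectors, one per valid
#'   centre, centre included).
#' @export
window_geometry <- function(roi_mask) {
  d <- dim(roi_mask)
  stopifnot(length(d) == 3)
  roi <- roi_mask != 0
  coords <- which(roi, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0) stop("ROI is empty")
  nb <- matrix(NA_integer_, n, 27)
  k <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    p1 <- coords[, 1] + dx
    p2 <- coords[, 2] + dy
    p3 <- coords[, 3] + dz
    ok <- p1 >= 1 & p1 <= d[1] & p2 >= 1 & p2 <= d[2] & p3 >= 1 & p3 <= d[3]
    lin <- p1 + (p2 - 1L) * d[1] + (p3 - 1L) * d[1] * d[2]
    ok[ok] <- roi[lin[ok]]
    nb[ok, k] <- lin[ok]
  }
  cnt <- rowSums(!is.na(nb))
  valid <- cnt >= 2
  centres <- coords[, 1] + (coords[, 2] - 1L) * d[1] + (coords[, 3] - 1L) * d[1] * d[2]
  neighbors <- lapply(which(valid), function(i) nb[i, !is.na(nb[i, ])])
  list(dim = d, vox_idx = centres[valid], neighbors = neighbors)
}

#' Sliding-window feature maps for one BOLD run
#'
#' Walks the 3x3x3 sliding window over every ROI voxel of a BOLD run (frames
#' already discarded), forms the window time-series bundle (mean series plus
#' individual voxel series), and evaluates the full 85-feature vector at each
#' valid window centre.
#'
#' @param bold_run 4D array on the ROI grid with stabilisation frames already
#'   discarded.
#' @param roi_mask binary 3D array on the same grid.
#' @param tr repetition time in seconds.
#' @param run_id identifier stored with the result.
#' @param geometry optional precomputed [window_geometry()] (reused across
#'   runs of the same subject).
#' @param max_order maximum AR order.
#' @return A `feature_map_set`: list with `run_id`, `dim`, `vox_idx`,
#'   `values` (windows x 85 matrix) and `features`.
#' @export
sliding_window_maps <- function(bold_run, roi_mask, tr = 2, run_id = "run1",
                                geometry = NULL, max_order = 8) {
  d <- dim(bold_run)
  stopifnot(length(d) == 4)
  if (!identical(d[1:3], dim(roi_mask)))
    stop("BOLD run and ROI mask must share a grid")
  if (d[4] < 8) stop("run must have at least 8 frames after discard")
  if (is.null(geometry)) geometry <- window_geometry(roi_mask)

  nt <- d[4]
  V <- matrix(bold_run, prod(d[1:3]), nt)
  W <- length(geometry$vox_idx)
  M <- matrix(0, nt, W)
  vox_list <- vector("list", W)
  for (w in seq_len(W)) {
    s <- t(V[geometry$neighbors[[w]], , drop = FALSE])
    vox_list[[w]] <- s
    M[, w] <- rowMeans(s)
  }
  vals <- window_feature_matrix(M, vox_list, tr, max_order = max_order)
  structure(list(run_id = run_id, dim = geometry$dim,
                 vox_idx = geometry$vox_idx, values = vals,
                 features = colnames(vals)),
            class = "feature_map_set")
}

#' Materialise one feature of a feature-map set as a 3D volume
#'
#' @param fms a `feature_map_set`.
#' @param feature feature name.
#' @return 3D array, `NA` at invalid voxels.
#' @export
as_volume <- function(fms, feature) {
  stopifnot(inherits(fms, "feature_map_set"), feature %in% fms$features)
  vol <- array(NA_real_, fms$dim)
  vol[fms$vox_idx] <- fms$values[, feature]
  vol
}

#' z-score a map within the ROI
#'
#' Standardises the in-ROI valid values of a 3D volume to mean 0, SD 1
#' (per-subject standardisation before fusion). Voxels outside the ROI are
#' untouched.
#'
#' @param map numeric 3D array.
#' @param roi_mask binary 3D array on the same grid.
#' @param feature label used in error messages.
#' @return The standardised 3D array.
#' @export
zscore_map <- function(map, roi_mask, feature = "map") {
  if (!identical(dim(map), dim(roi_mask))) stop("map and ROI grid mismatch")
  idx <- which(roi_mask != 0 & !is.na(map))
  v <- map[idx]
  if (length(v) < 2) stop("need at least 2 valid in-ROI values for ", feature)
  s <- stats::sd(v)
  if (s == 0) stop("zero spread in feature '", feature, "'; cannot z-score")
  map[idx] <- (v - mean(v)) / s
  map
}

#' z-score every feature column of a feature-map set
#'
#' @param fms a `feature_map_set`.
#' @return The set with each feature column standardised over valid voxels.
#' @export
zscore_fms <- function(fms) {
  stopifnot(inherits(fms, "feature_map_set"))
  mu <- colMeans(fms$values)
  s <- apply(fms$values, 2, stats::sd)
  if (any(s == 0))
    stop("zero spread in feature '", fms$features[which(s == 0)[1]],
         "'; cannot z-score")
  fms$values <- sweep(sweep(fms$values, 2, mu), 2, s, "/")
  fms
}

#' Aggregate feature-map sets across runs
#'
#' Voxel-wise mean over runs (typically of per-run z-scored maps); all sets
#' must share the grid and window geometry.
#'
#' @param maps list of `feature_map_set` objects.
#' @return A single `feature_map_set` with `run_id = "aggregate"`.
#' @export
aggregate_runs <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  for (m in maps) {
    stopifnot(inherits(m, "feature_map_set"))
    if (!identical(m$dim, ref$dim) || !identical(m$vox_idx, ref$vox_idx))
      stop("feature-map sets must share grid and window geometry")
  }
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  structure(list(run_id = "aggregate", dim = ref$dim, vox_idx = ref$vox_idx,
                 values = vals, features = ref$features),
            class = "feature_map_set")
}
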