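# Subject-level split-and-swap evaluation of the three contender models.

#' Random 50/50 subject-level split and its swap
#'
#' Subjects (never scans) are partitioned at random into train and test
#' halves; with an odd count the training half gets the extra subject. The
#' swapped split exchanges the two sets so every subject is tested exactly
#' once across the pair.
#'
#' @param subject_ids character vector (>= 2 subjects).
#' @param seed RNG seed for the partition.
#' @return List of two `cohort_split`s (`original`, `swapped`), each with
#'   `train`, `test`, `label`, `seed`.
#' @export
make_splits <- function(subject_ids, seed = 1) {
  n <- length(subject_ids)
  if (n < 2) stop("need at least 2 subjects to split")
  perm <- .with_seed(seed, sample(subject_ids))
  n_train <- ceiling(n / 2)
  orig <- structure(list(train = sort(perm[seq_len(n_train)]),
                         test = sort(perm[-seq_len(n_train)]),
                         label = "original", seed = seed),
                    class = "cohort_split")
  swap <- structure(list(train = orig$test, test = orig$train,
                         label = "swapped", seed = seed),
                    class = "cohort_split")
  list(original = orig, swapped = swap)
}

# per-subject fusion design from an extraction: z-scored probability map,
# z-scored + zero-clipped selected feature maps (aggregated over runs and
# per run), truth labels -- all at the valid window voxels
.fusion_design <- function(extract, selected) {
  idx <- extract$geometry$vox_idx
  zs <- function(v, label) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) stop("zero spread in ", label)
    (v - mean(v)) / s
  }
  prob_z <- zs(extract$probmap_ds[idx], "probability map")
  feats_run <- lapply(extract$fms_runs, function(fms) {
    m <- fms$values[, selected$feature, drop = FALSE]
    for (j in seq_len(ncol(m)))
      m[, j] <- zs(m[, j], selected$feature[j])
    m
  })
  agg <- Reduce(`+`, feats_run) / length(feats_run)
  clip <- function(m) {
    for (j in seq_len(ncol(m))) m[, j] <- zero_clip(m[, j], selected$sign[j])
    m
  }
  list(subject_id = extract$subject_id,
       prob_raw = extract$probmap_ds[idx],
       prob_z = prob_z,
       feats = clip(agg),
       feats_run = lapply(feats_run, clip),
       truth = extract$lesion_ds[idx] != 0)
}

#' Three-contender model comparison on one split
#'
#' Screens features on the training subjects, fits the re-optimised
#' (probability-map-only) and multivariate logistic fusion models on the
#' training half by full-grid search, and scores all three contenders --
#' original thresholded probability map, re-optimised model, multivariate
#' model -- on every subject. The multivariate model is additionally applied
#' per run, and the across-run SD of the per-run Dice is reported.
#'
#' @param extracts named list of [extract_subject_maps()] results (names =
#'   subject ids), one visit.
#' @param split a `cohort_split`.
#' @param k number of rs-fMRI features in the multivariate model (default 2).
#' @param grid_multi,grid_reopt grids for the two fitted contenders.
#' @return data.frame: `model`, `split`, `subject_id`, `role`
#'   (train/test), `dice`, `dice_sd` (across runs; NA for single-map
#'   models); the fitted parameter objects and the training ranking are in
#'   attributes `params_multi`, `params_reopt`, `ranking`.
#' @export
compare_models <- function(extracts, split, k = 2,
                           grid_multi = fusion_grid(k),
                           grid_reopt = fusion_grid(0)) {
  ids <- names(extracts)
  missing_ids <- setdiff(c(split$train, split$test), ids)
  if (length(missing_ids) > 0)
    stop("no extracted maps for subject ", missing_ids[1])
  ranking <- rank_features(
    cohort_fisher_tables(extracts[split$train]))
  selected <- select_top(ranking, k)
  designs <- lapply(extracts, .fusion_design, selected = selected)

  fit_multi <- grid_search_fit(designs[split$train], grid_multi, n_features = k)
  fit_reopt <- grid_search_fit(designs[split$train], grid_reopt, n_features = 0)

  rows <- lapply(ids, function(id) {
    d <- designs[[id]]
    role <- if (id %in% split$test) "test" else "train"
    orig <- dice_index(d$prob_raw > 0.5, d$truth)$dice
    reopt <- apply_model(fit_reopt, d)$dice$dice
    multi <- apply_model(fit_multi, d)$dice$dice
    # across-run variability: the fitted model applied to each run's maps
    per_run <- vapply(d$feats_run, function(fr) {
      dr <- d
      dr$feats <- fr
      apply_model(fit_multi, dr)$dice$dice
    }, numeric(1))
    data.frame(model = c("original", "reoptimized", "multivariate"),
               split = split$label, subject_id = id, role = role,
               dice = c(orig, reopt, multi),
               dice_sd = c(NA_real_, NA_real_, stats::sd(per_run)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "params_multi") <- fit_multi
  attr(out, "params_reopt") <- fit_reopt
  attr(out, "ranking") <- ranking
  out
}

#' Mean and SD of per-subject Dice values per model
#'
#' The aggregation path used for all reported cohort means.
#'
#' @param result a [compare_models()] table (or any data.frame with `model`
#'   and `dice`; if a `role` column is present only test rows are used).
#' @return data.frame with `model`, `n`, `mean_dice`, `sd_dice`.
#' @export
summarize_dice_table <- function(result) {
  if ("role" %in% names(result)) result <- result[result$role == "test", ]
  agg <- lapply(split(result$dice, result$model), function(v)
    c(n = length(v), mean_dice = mean(v), sd_dice = stats::sd(v)))
  out <- data.frame(model = names(agg), do.call(rbind, agg),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Average the two splits' test means for final reporting
#'
#' @param original_result,swapped_result [compare_models()] tables for the
#'   original and swapped split.
#' @return data.frame with `model`, the two per-split test means, and their
#'   average `mean_dice`.
#' @export
average_splits <- function(original_result, swapped_result) {
  a <- summarize_dice_table(original_result)
  b <- summarize_dice_table(swapped_result)
  m <- match(a$model, b$model)
  data.frame(model = a$model,
             mean_original = a$mean_dice,
             mean_swapped = b$mean_dice[m],
             mean_dice = (a$mean_dice + b$mean_dice[m]) / 2,
             stringsAsFactors = FALSE)
}

#' Two-sided paired t-test
#'
#' Thin wrapper around [stats::t.test()] with an explicit degenerate-case
#' contract: if the paired differences have zero variance the result is
#' flagged, with t = 0, p = 1 when the vectors are identical.
#'
#' @param dice_a,dice_b equal-length paired numeric vectors (n >= 2).
#' @return List with `t`, `p`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_t_test <- function(dice_a, dice_b) {
  if (length(dice_a) != length(dice_b)) stop("paired vectors differ in length")
  if (length(dice_a) < 2) stop("need at least 2 pairs")
  d <- dice_a - dice_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, mean_diff = 0, n = length(d),
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_diff = mean(d),
                n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(dice_a, dice_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), n = length(d), degenerate = FALSE)
}

#' Run the full split-and-swap evaluation for one visit
#'
#' @param extracts named list of [extract_subject_maps()] results.
#' @param seed split seed.
#' @param k number of rs-fMRI features for the multivariate contender.
#' @return List with the two [compare_models()] tables, the averaged report,
#'   and the paired t-test of multivariate vs re-optimised test Dice (paired
#'   over all subjects, each tested once across the two splits).
#' @export
evaluate_visit <- function(extracts, seed = 1, k = 2) {
  splits <- make_splits(names(extracts), seed = seed)
  res_o <- compare_models(extracts, splits$original, k = k)
  res_s <- compare_models(extracts, splits$swapped, k = k)
  both <- rbind(res_o, res_s)
  test_rows <- both[both$role == "test", ]
  wide <- split(test_rows, test_rows$model)
  ord <- order(wide$multivariate$subject_id)
  tt <- paired_t_test(
    wide$multivariate$dice[ord],
    wide$reoptimized$dice[order(wide$reoptimized$subject_id)])
  list(original_split = res_o, swapped_split = res_s,
       report = average_splits(res_o, res_s),
       t_multi_vs_reopt = tt, splits = splits)
}
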