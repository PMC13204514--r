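# Recovery-correlation analyses with family-wise error control.

#' Ordinary least-squares simple regression
#'
#' @param x,y finite numeric vectors, n >= 3; `x` must have nonzero variance.
#' @return A `regression_result` list: `slope`, `intercept`, `p` (two-sided
#'   slope t-test), `r2`, `n`.
#' @export
simple_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 finite (x, y) pairs")
  if (stats::sd(x) == 0) stop("x has zero variance; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p = sm$coefficients[2, 4],
                 r2 = sm$r.squared, n = length(x)),
            class = "regression_result")
}

#' Holm-Bonferroni step-wise thresholds
#'
#' The i-th smallest p-value in a family of m tests is compared against
#' `alpha / (m - i + 1)`; for m = 3 at alpha = 0.05 this gives
#' {0.0167, 0.025, 0.05}.
#'
#' @param m family size (>= 1).
#' @param alpha family-wise error rate.
#' @return Increasing numeric vector of m thresholds.
#' @export
holm_thresholds <- function(m, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / (m - seq_len(m) + 1)
}

#' Holm step-down significance flags
#'
#' Orders the p-values, compares each against its step-wise threshold and
#' stops at the first failure, so flags are monotone in the ordered
#' p-values.
#'
#' @param p numeric vector of p-values.
#' @param alpha family-wise error rate.
#' @return Logical vector aligned with `p`.
#' @export
holm_flags <- function(p, alpha = 0.05) {
  m <- length(p)
  thr <- holm_thresholds(m, alpha)
  ord <- order(p)
  flags_ord <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= thr[i]) flags_ord[i] <- TRUE else break
  }
  flags <- logical(m)
  flags[ord] <- flags_ord
  flags
}

#' Per-subject biomarker amplitude summaries
#'
#' The per-subject scalar used by the recovery analyses: the mean Fisher
#' score of the chosen biomarker over the visit's runs.
#'
#' @param extracts named list of [extract_subject_maps()] results (one
#'   visit).
#' @param feature biomarker name (default the spectral peak amplitude).
#' @return data.frame with `subject_id`, `amplitude`.
#' @export
amplitude_summary <- function(extracts, feature = "spec_peak_amp") {
  rows <- lapply(extracts, function(e) {
    sc <- vapply(e$fms_runs, function(fms) {
      tb <- fisher_scores_fms(fms, e$lesion_ds, e$wm_ds)
      tb$score[tb$feature == feature]
    }, numeric(1))
    data.frame(subject_id = e$subject_id, amplitude = mean(sc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The two recovery-correlation test families
#'
#' Family 1 (prognostic) regresses each assessment change on the subacute
#' biomarker amplitude; family 2 (longitudinal change) regresses each
#' assessment change on the amplitude change between visits. Each family of
#' three tests (FIM Walk, word comprehension, Posner cueing) is controlled
#' at the given family-wise error rate with the Holm-Bonferroni method,
#' separately per family. Only chronic completers enter.
#'
#' @param amplitudes data.frame with `subject_id`, `subacute`, `chronic`
#'   biomarker amplitude summaries (chronic may be NA for non-completers).
#' @param assessments assessment table from [generate_assessments()].
#' @param alpha family-wise error rate (default 0.05).
#' @param families which families to run (`"prognostic"` needs only subacute
#'   amplitudes; `"longitudinal_change"` also needs chronic amplitudes).
#' @return Named list of `family_report` data.frames (`prognostic`,
#'   `longitudinal_change`) with columns `independent`, `dependent`, `slope`,
#'   `p`, `r2`, `n`, `threshold`, `flagged`; step-wise thresholds in
#'   `attr(, "thresholds")`.
#' @export
run_families <- function(amplitudes, assessments, alpha = 0.05,
                         families = c("prognostic", "longitudinal_change")) {
  families <- match.arg(families, several.ok = TRUE)
  ch <- assessment_changes(assessments)
  m <- match(ch$subject_id, amplitudes$subject_id)
  ch$amp_sub <- amplitudes$subacute[m]
  ch$amp_change <- amplitudes$chronic[m] - amplitudes$subacute[m]

  deps <- c(fim_walk = "d_fim", word_comprehension = "d_word",
            posner_ms = "d_posner")
  family <- function(xvar, label) {
    dat <- ch[stats::complete.cases(ch[c(xvar, unname(deps))]), ]
    if (nrow(dat) < 3) stop("need at least 3 chronic completers")
    fits <- lapply(deps, function(d) simple_regression(dat[[xvar]], dat[[d]]))
    p <- vapply(fits, `[[`, numeric(1), "p")
    thr <- holm_thresholds(length(p), alpha)
    rep <- data.frame(independent = label, dependent = names(deps),
                      slope = vapply(fits, `[[`, numeric(1), "slope"),
                      p = p,
                      r2 = vapply(fits, `[[`, numeric(1), "r2"),
                      n = vapply(fits, `[[`, numeric(1), "n"),
                      threshold = thr[rank(p, ties.method = "first")],
                      flagged = holm_flags(p, alpha),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(rep, "thresholds") <- thr
    class(rep) <- c("family_report", "data.frame")
    rep
  }
  out <- list()
  if ("prognostic" %in% families)
    out$prognostic <- family("amp_sub", "subacute_amplitude")
  if ("longitudinal_change" %in% families)
    out$longitudinal_change <- family("amp_change", "amplitude_change")
  out
}

#' Paired test of biomarker decline between visits
#'
#' Paired t-test of per-subject biomarker amplitude summaries (mean Fisher
#' scores) at the subacute versus chronic visit.
#'
#' @param subacute_scores,chronic_scores paired per-subject values.
#' @return As [paired_t_test()].
#' @export
amplitude_decline_test <- function(subacute_scores, chronic_scores) {
  paired_t_test(subacute_scores, chronic_scores)
}
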