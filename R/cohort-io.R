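# On-disk representation of a cohort: NIfTI volumes, CSV assessments, JSON
# manifest. Round-trips losslessly through read_cohort().

#' Write a cohort to disk
#'
#' Writes one NIfTI file per mask/probability map/BOLD run, the assessment
#' table as CSV, and a JSON manifest (subject ids, visit labels, planted
#' parameters, seeds, file listing).
#'
#' @param cohort a `stroke_cohort`.
#' @param directory output directory (created if needed).
#' @param assessments optional table from [generate_assessments()].
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cohort, directory, assessments = NULL) {
  stopifnot(inherits(cohort, "stroke_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create output directory: ", directory)
  subj_entries <- lapply(cohort$subjects, function(s) {
    id <- s$subject_id
    files <- list(
      wm_mask = paste0(id, "_wm.nii.gz"),
      lesion_mask = paste0(id, "_lesion.nii.gz"),
      probmap = paste0(id, "_probmap.nii.gz"))
    RNifti::writeNifti(s$wm_mask, file.path(directory, files$wm_mask))
    RNifti::writeNifti(s$lesion_mask, file.path(directory, files$lesion_mask))
    RNifti::writeNifti(s$probmap, file.path(directory, files$probmap))
    bold <- list()
    for (v in s$visits) {
      bold[[v]] <- vapply(seq_along(s$bold_runs[[v]]), function(r) {
        fn <- sprintf("%s_%s_run-%d_bold.nii.gz", id, v, r)
        RNifti::writeNifti(s$bold_runs[[v]][[r]], file.path(directory, fn))
        fn
      }, character(1))
    }
    list(subject_id = id, visits = as.list(s$visits), files = files,
         bold_files = bold, contrasts = as.list(s$contrasts),
         injected_freq_hz = s$injected_freq_hz,
         injected_bin = s$injected_bin,
         probmap_target_dice = s$probmap_target_dice, seed = s$seed)
  })
  if (!is.null(assessments))
    utils::write.csv(assessments,
                     file.path(directory, "assessments.csv"),
                     row.names = FALSE)
  manifest <- list(config = unclass(cohort$config),
                   completers = cohort$completers,
                   has_assessments = !is.null(assessments),
                   subjects = subj_entries)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort back from disk
#'
#' @param directory directory written by [write_cohort()].
#' @return A `stroke_cohort`; if an assessment table was written it is
#'   attached as `$assessments`.
#' @export
read_cohort <- function(directory) {
  mf_path <- file.path(directory, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", directory)
  mf <- jsonlite::read_json(mf_path)
  cfg_args <- lapply(mf$config, function(x) if (is.list(x)) unlist(x) else x)
  config <- do.call(cohort_config, cfg_args)
  rd <- function(fn) {
    p <- file.path(directory, fn)
    if (!file.exists(p)) stop("missing cohort file: ", p)
    as.array(RNifti::readNifti(p))
  }
  subjects <- lapply(mf$subjects, function(e) {
    visits <- unlist(e$visits)
    bold <- lapply(stats::setNames(visits, visits), function(v)
      lapply(unlist(e$bold_files[[v]]), rd))
    structure(list(subject_id = e$subject_id,
                   wm_mask = rd(e$files$wm_mask),
                   lesion_mask = rd(e$files$lesion_mask),
                   probmap = rd(e$files$probmap),
                   bold_runs = bold, visits = visits,
                   contrasts = unlist(e$contrasts),
                   injected_freq_hz = e$injected_freq_hz,
                   injected_bin = e$injected_bin,
                   probmap_target_dice = e$probmap_target_dice,
                   seed = e$seed),
              class = "subject_bundle")
  })
  cohort <- structure(list(config = config, subjects = subjects,
                           completers = as.integer(unlist(mf$completers))),
                      class = "stroke_cohort")
  csv <- file.path(directory, "assessments.csv")
  if (file.exists(csv))
    cohort$assessments <- utils::read.csv(csv, stringsAsFactors = FALSE)
  cohort
}
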