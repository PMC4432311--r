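#' Cohort CSV input/output
#'
#' The cohort travels as two CSVs with documented columns:
#' * `patients.csv` — `patient_id, pair_id, group, age, race,
#'   gleason_primary, gleason_secondary, ptnm, psa_ng_ml, margins, svi,
#'   ece, lni, g_mean, n_rois`
#' * `rois.csv` — long format, `patient_id, roi_id, g`
#'
#' @param cohort a `qpi_cohort` (see [gen_cohort()]).
#' @param dir output directory (created if needed).
#' @return `write_cohort_csv`: the paths written (invisibly);
#'   `read_cohort_csv`: a `qpi_cohort`.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!inherits(cohort, "qpi_cohort"))
    stop_parameter("`cohort` must be a qpi_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop_io(sprintf("cannot create directory %s", dir))
  pp <- file.path(dir, "patients.csv")
  rp <- file.path(dir, "rois.csv")
  utils::write.csv(cohort$patients, pp, row.names = FALSE)
  utils::write.csv(cohort$rois, rp, row.names = FALSE)
  invisible(c(patients = pp, rois = rp))
}

#' @rdname cohort-io
#' @param patients_csv,rois_csv file paths.
#' @export
read_cohort_csv <- function(patients_csv, rois_csv) {
  for (f in c(patients_csv, rois_csv))
    if (!file.exists(f)) stop_io(sprintf("cohort file not found: %s", f))
  patients <- utils::read.csv(patients_csv, stringsAsFactors = FALSE)
  rois <- utils::read.csv(rois_csv, stringsAsFactors = FALSE)
  need_p <- c("patient_id", "group")
  if (!all(need_p %in% names(patients)))
    stop_data(sprintf("patients CSV must have columns %s",
                      paste(need_p, collapse = ", ")))
  need_r <- c("patient_id", "roi_id", "g")
  if (!all(need_r %in% names(rois)))
    stop_data(sprintf("rois CSV must have columns %s",
                      paste(need_r, collapse = ", ")))
  for (col in c("margins", "svi", "ece", "lni"))
    if (col %in% names(patients)) patients[[col]] <- as.logical(patients[[col]])
  structure(list(patients = patients, rois = rois), class = "qpi_cohort")
}
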