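#' @title Signal and cohort file formats
#' @description Signals travel as two-column CSV (`time_s`,
#'   `pressure_mmHg`) with a JSON sidecar carrying metadata (patient id,
#'   channel, sampling rate, site, and the ground-truth block for synthetic
#'   signals). Cohorts are a directory of such pairs plus a manifest CSV.
#' @name signal-io
NULL

#' Write a waveform to CSV with JSON sidecar
#'
#' @param w A `pressure_waveform`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param patient_id,site Metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_signal <- function(w, path, patient_id = NA, site = NA) {
  stopifnot(inherits(w, "pressure_waveform"))
  utils::write.csv(data.frame(time_s = waveform_time(w),
                              pressure_mmHg = w$samples),
                   path, row.names = FALSE)
  meta <- list(patient_id = patient_id, channel = w$channel,
               sampling_rate_hz = w$sampling_rate, t0 = w$t0, site = site)
  gt <- attr(w, "ground_truth")
  strip_s3 <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip_s3))
    x
  }
  if (!is.null(gt)) meta$ground_truth <- strip_s3(gt)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", na = "null")
  invisible(path)
}

#' Read a waveform written by [write_signal()]
#'
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return A `pressure_waveform`.
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop("no such signal file: ", path, call. = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side, call. = FALSE)
  d <- utils::read.csv(path)
  if (!all(c("time_s", "pressure_mmHg") %in% names(d)) || nrow(d) < 2L)
    stop("malformed signal file: ", path, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  gt <- meta$ground_truth
  if (!is.null(gt) && !is.null(gt$beats))
    gt$beats <- as.data.frame(gt$beats)
  pressure_waveform(d$pressure_mmHg, meta$sampling_rate_hz,
                    channel = meta$channel,
                    t0 = if (is.null(meta$t0)) 0 else meta$t0,
                    ground_truth = gt)
}

#' Write a cohort as a signal directory plus manifest
#'
#' Per patient: `<id>_invasive.csv`, `<id>_cuff.csv`, `<id>_flush.csv`
#' (each with sidecar), plus `manifest.csv` with patient ids, file paths,
#' sites, and the true and device central pressures.
#'
#' @param cohort A `cbp_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cbp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$patients, function(p) {
    paths <- c(invasive = file.path(dir, paste0(p$patient_id, "_invasive.csv")),
               cuff = file.path(dir, paste0(p$patient_id, "_cuff.csv")),
               flush = file.path(dir, paste0(p$patient_id, "_flush.csv")))
    write_signal(p$invasive, paths["invasive"], p$patient_id, p$site)
    write_signal(p$cuff, paths["cuff"], p$patient_id, p$site)
    if (!is.null(p$flush))
      write_signal(p$flush, paths["flush"], p$patient_id, p$site)
    data.frame(patient_id = p$patient_id, site = p$site,
               status = p$status,
               invasive_path = basename(paths[["invasive"]]),
               cuff_path = basename(paths[["cuff"]]),
               flush_path = if (is.null(p$flush)) "" else
                 basename(paths[["flush"]]),
               true_sbp = p$true_cbp[["sbp"]], true_map = p$true_cbp[["map"]],
               true_dbp = p$true_cbp[["dbp"]],
               device_sbp = p$device_cbp[["sbp"]],
               device_map = p$device_cbp[["map"]],
               device_dbp = p$device_cbp[["dbp"]])
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Unreadable or malformed signal files are itemized as load errors: the
#' affected channel is set to `NULL` (the runner then excludes the patient
#' as incomplete) and the messages are attached as attribute
#' `"load_errors"`.
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @return A `cbp_cohort`.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  mf <- utils::read.csv(mf_path)
  errors <- character(0)
  load1 <- function(path, id, what) {
    if (is.na(path) || path == "") return(NULL)
    tryCatch(read_signal(file.path(dir, path)), error = function(e) {
      errors <<- c(errors, sprintf("%s/%s: %s", id, what,
                                   conditionMessage(e)))
      NULL
    })
  }
  patients <- lapply(seq_len(nrow(mf)), function(i) {
    r <- mf[i, ]
    list(patient_id = r$patient_id, site = r$site,
         status = if ("status" %in% names(mf)) r$status else NA,
         invasive = load1(r$invasive_path, r$patient_id, "invasive"),
         cuff = load1(r$cuff_path, r$patient_id, "cuff"),
         flush = load1(r$flush_path, r$patient_id, "flush"),
         true_cbp = c(sbp = r$true_sbp, map = r$true_map,
                      dbp = r$true_dbp),
         device_cbp = c(sbp = r$device_sbp, map = r$device_map,
                        dbp = r$device_dbp),
         hr = NA_real_)
  })
  out <- structure(list(spec = NULL, patients = patients, manifest = mf),
                   class = "cbp_cohort")
  if (length(errors) > 0) attr(out, "load_errors") <- errors
  out
}
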