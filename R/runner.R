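#' @title End-to-end study orchestration
#' @description Runs the full validation pipeline over a cohort: per-patient
#'   invasive beat analysis with outlier clearing and exclusion rules,
#'   signal-integrity (plausibility) screening, central-pressure estimation
#'   (either the recorded device estimates or the oscillometric surrogate
#'   chain), agreement statistics, protocol grading, range conformity and a
#'   machine-readable study report.
#' @name study-runner
NULL

#' Study configuration
#'
#' @param sd_limits Hemodynamic-stability SD limits, mmHg
#'   (`c(sbp = 10, map = 6, dbp = 6)`).
#' @param arrhythmia_threshold Maximum cleared-beat fraction (strict,
#'   default 0.30).
#' @param outlier_k Beat outlier-clearing threshold in robust-SD units
#'   (default 3).
#' @param estimator `"device"` uses the device estimates recorded with the
#'   cohort (validation of an external estimator); any registered estimator
#'   id (e.g. `"ratio_surrogate"`) runs the oscillometric chain instead.
#' @param systolic_ratio,diastolic_ratio Characteristic ratios for
#'   [envelope_bp()] when the oscillometric chain is used.
#' @param fn_range,zeta_range Flush-test QC acceptance ranges.
#' @param plausible_dbp,plausible_sbp Plausibility limits, mmHg: a recording
#'   whose mean DBP falls below `plausible_dbp` or mean SBP above
#'   `plausible_sbp` is excluded as corrupt (e.g. a zeroing error).
#' @param rng_seed Seed recorded in the report provenance.
#' @return A `study_config` list.
#' @export
study_config <- function(sd_limits = c(sbp = 10, map = 6, dbp = 6),
                         arrhythmia_threshold = 0.30,
                         outlier_k = 3,
                         estimator = "device",
                         systolic_ratio = 0.55, diastolic_ratio = 0.70,
                         fn_range = c(15, 29), zeta_range = c(0.14, 0.29),
                         plausible_dbp = 30, plausible_sbp = 300,
                         rng_seed = 1L) {
  stopifnot(all(sd_limits > 0), arrhythmia_threshold > 0)
  if (estimator != "device") get_estimator(estimator)  # must be registered
  structure(list(sd_limits = sd_limits,
                 arrhythmia_threshold = arrhythmia_threshold,
                 outlier_k = outlier_k, estimator = estimator,
                 systolic_ratio = systolic_ratio,
                 diastolic_ratio = diastolic_ratio,
                 fn_range = fn_range, zeta_range = zeta_range,
                 plausible_dbp = plausible_dbp,
                 plausible_sbp = plausible_sbp,
                 rng_seed = as.integer(rng_seed)),
            class = "study_config")
}

#' Exclusion accounting table
#'
#' Tallies patient verdicts by reason, with stability sub-reasons (which SD
#' triggered) attributed in the order SBP, MAP, DBP, and reconciles the
#' totals.
#'
#' @param verdicts Data.frame with columns `patient_id`, `verdict`
#'   (`include`, `exclude_arrhythmia`, `exclude_stability`,
#'   `exclude_corrupt`, `exclude_incomplete`) and `detail`.
#' @return List `table` (reason, count), `recorded`, `analyzed`; errors on
#'   duplicate patient ids and asserts `analyzed = recorded - excluded`.
#' @export
exclusion_ledger <- function(verdicts) {
  if (anyDuplicated(verdicts$patient_id))
    stop("duplicate patient ids", call. = FALSE)
  recorded <- nrow(verdicts)
  reasons <- c(stability_sbp_sd = sum(verdicts$verdict == "exclude_stability" &
                                        verdicts$detail == "sd_sbp"),
               stability_map_sd = sum(verdicts$verdict == "exclude_stability" &
                                        verdicts$detail == "sd_map"),
               stability_dbp_sd = sum(verdicts$verdict == "exclude_stability" &
                                        verdicts$detail == "sd_dbp"),
               arrhythmia = sum(verdicts$verdict == "exclude_arrhythmia"),
               corrupt = sum(verdicts$verdict == "exclude_corrupt"),
               incomplete = sum(verdicts$verdict == "exclude_incomplete"))
  analyzed <- sum(verdicts$verdict == "include")
  stopifnot(analyzed == recorded - sum(reasons))
  list(table = data.frame(reason = names(reasons),
                          count = as.integer(reasons)),
       recorded = recorded, analyzed = analyzed)
}

#' Run the full validation study on a cohort
#'
#' For every patient: load both channels (a missing channel excludes the
#' patient as incomplete, never crashes), screen for signal integrity,
#' run the invasive per-beat analysis and the recording-level exclusion
#' rules, obtain the estimated central pressures, and finally compute
#' Bland-Altman agreement, error bins, protocol grades and range
#' conformity over the included patients.
#'
#' @param cohort A `cbp_cohort` from [synth_cohort()] or [read_cohort()].
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, the report is written as
#'   JSON plus tidy CSV tables and per-component plot-data files.
#' @return A `study_report` list: `cohort_table`, `exclusions`, `pairs`,
#'   `agreement` (per component), `grading`, `range_conformity`,
#'   `provenance`.
#' @export
run_study <- function(cohort, config = study_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "cbp_cohort"), inherits(config, "study_config"))
  n <- length(cohort$patients)
  verdicts <- data.frame(patient_id = character(n), verdict = character(n),
                         detail = character(n))
  inv_tab <- matrix(NA_real_, n, 6,
                    dimnames = list(NULL, c("inv_sbp", "inv_map", "inv_dbp",
                                            "est_sbp", "est_map", "est_dbp")))
  sd_tab <- matrix(NA_real_, n, 3,
                   dimnames = list(NULL, c("sd_sbp", "sd_map", "sd_dbp")))
  hr_est <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    p <- cohort$patients[[i]]
    verdicts$patient_id[i] <- p$patient_id
    if (is.null(p$invasive) || is.null(p$cuff)) {
      verdicts$verdict[i] <- "exclude_incomplete"
      verdicts$detail[i] <- "missing channel"
      next
    }
    ana <- tryCatch(
      analyze_invasive(p$invasive, k = config$outlier_k,
                       sd_limits = config$sd_limits,
                       arrhythmia_threshold = config$arrhythmia_threshold),
      error = function(e) NULL)
    if (is.null(ana)) {
      verdicts$verdict[i] <- "exclude_corrupt"
      verdicts$detail[i] <- "invasive analysis failed"
      next
    }
    s <- ana$summary
    hr_est[i] <- 60 * (s$n_beats_total) /
      waveform_duration(p$invasive)
    # signal-integrity screen before the physiologic exclusion rules
    if (s$mean_dbp < config$plausible_dbp ||
        s$mean_sbp > config$plausible_sbp) {
      verdicts$verdict[i] <- "exclude_corrupt"
      verdicts$detail[i] <- "implausible pressures (zeroing error?)"
      next
    }
    verdicts$verdict[i] <- ana$verdict
    verdicts$detail[i] <- ana$detail
    if (ana$verdict != "include") next

    inv_tab[i, 1:3] <- c(s$mean_sbp, s$mean_map, s$mean_dbp)
    sd_tab[i, ] <- c(s$sd_sbp, s$sd_map, s$sd_dbp)
    est <- if (config$estimator == "device") {
      if (is.null(p$device_cbp))
        stop("estimator 'device' needs device estimates in the cohort",
             call. = FALSE)
      p$device_cbp[c("sbp", "map", "dbp")]
    } else {
      osc <- tryCatch(
        analyze_oscillometric(p$cuff, estimator = config$estimator,
                              systolic_ratio = config$systolic_ratio,
                              diastolic_ratio = config$diastolic_ratio),
        error = function(e) NULL)
      if (is.null(osc)) {
        verdicts$verdict[i] <- "exclude_corrupt"
        verdicts$detail[i] <- "oscillometric analysis failed"
        inv_tab[i, ] <- NA_real_
        next
      }
      c(sbp = osc$central$csbp, map = osc$central$cmap,
        dbp = osc$central$cdbp)
    }
    inv_tab[i, 4:6] <- est
  }

  excl <- exclusion_ledger(verdicts)
  inc <- verdicts$verdict == "include"
  pairs <- paired_measurements(
    patient_id = verdicts$patient_id,
    invasive = data.frame(sbp = inv_tab[, 1], map = inv_tab[, 2],
                          dbp = inv_tab[, 3]),
    estimated = data.frame(sbp = inv_tab[, 4], map = inv_tab[, 5],
                           dbp = inv_tab[, 6]),
    site = vapply(cohort$patients, function(p)
      if (is.null(p$site)) "unknown" else p$site, ""),
    included = inc,
    exclusion_reason = ifelse(inc, "", paste0(verdicts$verdict, ": ",
                                              verdicts$detail)))

  if (sum(inc) >= 2L) {
    agreement <- lapply(c("SBP", "MAP", "DBP"), function(cc)
      bland_altman(pairs, cc))
    names(agreement) <- c("SBP", "MAP", "DBP")
    grading <- grade_device(agreement)
  } else {
    # a single included pair has no dispersion: report it, flag degeneracy
    agreement <- NULL
    grading <- NULL
  }
  rc <- if (sum(inc) >= 1L)
    list(SBP = range_conformity(pairs$inv_sbp[inc], "SBP"),
         DBP = range_conformity(pairs$inv_dbp[inc], "DBP")) else NULL

  cohort_table <- if (sum(inc) < 1L) NULL else do.call(rbind, lapply(
    list(c("Invasive central SBP (mmHg)", "inv_sbp"),
         c("Invasive central MAP (mmHg)", "inv_map"),
         c("Invasive central DBP (mmHg)", "inv_dbp"),
         c("Estimated central SBP (mmHg)", "est_sbp"),
         c("Estimated central MAP (mmHg)", "est_map"),
         c("Estimated central DBP (mmHg)", "est_dbp")),
    function(e) {
      v <- pairs[[e[2]]][inc]
      data.frame(quantity = e[1], mean = mean(v), min = min(v),
                 max = max(v), sd = stats::sd(v))
    }))
  hrv <- hr_est[inc & !is.na(hr_est)]
  if (!is.null(cohort_table) && length(hrv) > 0)
    cohort_table <- rbind(cohort_table,
                          data.frame(quantity = "Heart rate (1/min)",
                                     mean = mean(hrv), min = min(hrv),
                                     max = max(hrv), sd = stats::sd(hrv)))

  report <- structure(list(
    cohort_table = cohort_table,
    stability = data.frame(patient_id = verdicts$patient_id,
                           sd_tab)[inc, , drop = FALSE],
    degenerate = sum(inc) < 2L,
    exclusions = excl,
    pairs = pairs,
    agreement = agreement,
    grading = grading,
    range_conformity = rc,
    provenance = list(
      config_hash = rlang::hash(unclass(config)),
      seed = config$rng_seed,
      estimator = config$estimator,
      package_version = tryCatch(
        as.character(utils::packageVersion("cbpval")),
        error = function(e) "dev"))
  ), class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d recorded, %d analyzed\n",
              x$exclusions$recorded, x$exclusions$analyzed))
  for (a in x$agreement) print(a)
  for (g in x$grading[c("SBP", "MAP", "DBP")]) print(g)
  invisible(x)
}

#' Write a study report to disk
#'
#' One JSON document plus tidy CSVs (`pairs.csv`, `exclusions.csv`,
#' `cohort_table.csv`) and per-component plot-data files with the scatter
#' and Bland-Altman points (`plotdata_<component>.csv`).
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- report$pairs
  utils::write.csv(pairs, file.path(out_dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions$table,
                   file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  utils::write.csv(report$cohort_table,
                   file.path(out_dir, "cohort_table.csv"),
                   row.names = FALSE)
  for (cc in c("SBP", "MAP", "DBP")) {
    suff <- tolower(cc)
    inc <- pairs$included
    inv <- pairs[[paste0("inv_", suff)]][inc]
    est <- pairs[[paste0("est_", suff)]][inc]
    utils::write.csv(
      data.frame(invasive = inv, estimated = est,
                 pair_mean = (inv + est) / 2, difference = inv - est),
      file.path(out_dir, sprintf("plotdata_%s.csv", suff)),
      row.names = FALSE)
  }
  json <- list(
    schema_version = "1.0",
    provenance = report$provenance,
    exclusions = c(list(recorded = report$exclusions$recorded,
                        analyzed = report$exclusions$analyzed),
                   stats::setNames(as.list(report$exclusions$table$count),
                                   report$exclusions$table$reason)),
    agreement = lapply(report$agreement, function(a)
      a[c("component", "n", "mean_diff", "sd_diff", "loa_lower",
          "loa_upper", "r", "r_squared", "slope", "intercept")]),
    grading = lapply(report$grading[c("SBP", "MAP", "DBP")], unclass),
    overall = report$grading$overall,
    range_conformity = lapply(report$range_conformity, function(r)
      list(n = r$n, recruitment_ratio_pct = r$recruitment_ratio_pct,
           table = r$table))
  )
  jsonlite::write_json(json, file.path(out_dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(out_dir)
}
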