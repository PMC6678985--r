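#' Cohort specification for the synthetic catheter-lab study
#'
#' Defaults reproduce the validation study's conditions: 191 patients
#' recruited across three sites (three recording profiles: 90 s at 240 Hz,
#' 90 s at 2000 Hz, 20 s at 500 Hz), invasive central pressures distributed
#' as in the study cohort, a per-component device-error model, and fixed
#' numbers of recordings failing the arrhythmia, stability and
#' signal-integrity rules so that exclusion accounting is exactly
#' reproducible.
#'
#' `device_error` parameterizes the distribution of invasive minus
#' estimated differences: the simulated device estimate is the true central
#' value minus a normal draw with the given mean and SD.
#'
#' @param n_patients Number of recruited patients (default 191).
#' @param bp_mean,bp_sd Named numeric (`sbp`, `map`, `dbp`): cohort means
#'   and SDs of the invasive central pressures, mmHg.
#' @param hr_mean_sd Numeric length 2: heart-rate mean and SD, beats/min.
#' @param device_error List with elements `sbp`, `map`, `dbp`, each
#'   `c(mean, sd)` in mmHg.
#' @param arrhythmia_fraction Fraction of patients with severe arrhythmia
#'   (default 22/191).
#' @param stability_fail_fraction Fraction failing hemodynamic stability
#'   (default 14/191), split across SBP/MAP/DBP sub-reasons 5:3:6.
#' @param corrupt_fraction Fraction with a corrupted recording emulating a
#'   zeroing error (default 10/191).
#' @param rng_seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 191,
                        bp_mean = c(sbp = 145.1, map = 101.5, dbp = 72.1),
                        bp_sd = c(sbp = 24.0, map = 14.8, dbp = 12.2),
                        hr_mean_sd = c(69.0, 12.2),
                        device_error = list(sbp = c(0.71, 5.95),
                                            map = c(0.19, 3.78),
                                            dbp = c(2.96, 5.21)),
                        arrhythmia_fraction = 22 / 191,
                        stability_fail_fraction = 14 / 191,
                        corrupt_fraction = 10 / 191,
                        rng_seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (any(bp_sd < 0) || hr_mean_sd[2] < 0 ||
      any(vapply(device_error, `[`, 0, 2) < 0))
    stop("all SDs must be >= 0", call. = FALSE)
  for (f in c(arrhythmia_fraction, stability_fail_fraction,
              corrupt_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (arrhythmia_fraction + stability_fail_fraction + corrupt_fraction > 1)
    stop("exclusion fractions must not sum above 1", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 bp_mean = bp_mean, bp_sd = bp_sd,
                 hr_mean_sd = hr_mean_sd, device_error = device_error,
                 arrhythmia_fraction = arrhythmia_fraction,
                 stability_fail_fraction = stability_fail_fraction,
                 corrupt_fraction = corrupt_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

# site recording profiles: duration (s) and sampling rate (Hz), with
# recruitment shares as in the study (63/50/32 of 145)
.site_profiles <- data.frame(
  site = c("site_A", "site_B", "site_C"),
  duration = c(90, 90, 20),
  sampling_rate = c(240, 2000, 500),
  share = c(63, 50, 32) / 145
)

#' Generate a synthetic paired cohort
#'
#' For each patient: an invasive aortic waveform, a simultaneous cuff
#' deflation recording, a flush test, the true central pressures (realized
#' per-beat means of the normal beats of the invasive ground truth), and a
#' simulated device estimate (truth minus a device-error draw). Patient
#' statuses (`normal`, `arrhythmia`, `stability_sbp/map/dbp`, `corrupt`)
#' are assigned in deterministic counts `round(fraction * n)` so exclusion
#' accounting is exact under any seed. All randomness flows from the spec's
#' seed; the same spec yields the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A `cbp_cohort`: list with `spec`, `patients` (list of records:
#'   `patient_id`, `site`, `status`, `invasive`, `cuff`, `flush`,
#'   `true_cbp`, `device_cbp`, `hr`) and `manifest` (one summary row per
#'   patient).
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  set.seed(spec$rng_seed)

  # deterministic status assignment, spread over the recruitment order
  n_arr <- round(spec$arrhythmia_fraction * n)
  n_stab <- round(spec$stability_fail_fraction * n)
  n_cor <- round(spec$corrupt_fraction * n)
  stab_split <- c(sbp = 5, map = 3, dbp = 6) / 14
  n_stab_c <- round(stab_split * n_stab)
  status <- rep("normal", n)
  special <- c(rep("arrhythmia", n_arr),
               rep("stability_sbp", n_stab_c[1]),
               rep("stability_map", n_stab_c[2]),
               rep("stability_dbp", n_stab_c[3]),
               rep("corrupt", n_cor))
  if (length(special) > 0) {
    pos <- round(seq(1, n, length.out = length(special)))
    status[pos] <- sample(special)
  }

  site_idx <- sample(seq_len(nrow(.site_profiles)), n, replace = TRUE,
                     prob = .site_profiles$share)

  # patient-level hemodynamics: correlated SBP/DBP, MAP at a jittered
  # fraction of pulse pressure (so dbp < map < sbp always holds)
  z_common <- stats::rnorm(n)
  rho <- 0.6
  sbp <- spec$bp_mean[["sbp"]] + spec$bp_sd[["sbp"]] *
    (rho * z_common + sqrt(1 - rho^2) * stats::rnorm(n))
  dbp <- spec$bp_mean[["dbp"]] + spec$bp_sd[["dbp"]] *
    (rho * z_common + sqrt(1 - rho^2) * stats::rnorm(n))
  sbp <- pmin(pmax(sbp, 84), 226)
  dbp <- pmin(pmax(dbp, 46), 107)
  pp <- pmax(sbp - dbp, 25); sbp <- dbp + pp
  f_map <- pmin(pmax(stats::rnorm(n, 0.40, 0.04), 0.28), 0.55)
  map <- dbp + f_map * pp
  hr <- pmin(pmax(stats::rnorm(n, spec$hr_mean_sd[1], spec$hr_mean_sd[2]),
                  40), 130)

  fn_flush <- pmin(pmax(stats::rnorm(n, 21.9, 3.5), 15), 29)
  z_flush <- pmin(pmax(stats::rnorm(n, 0.21, 0.037), 0.14), 0.29)

  err <- lapply(spec$device_error, function(e)
    stats::rnorm(n, e[1], e[2]))
  seeds <- sample.int(.Machine$integer.max - 10L, 3L * n)

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- .site_profiles[site_idx[i], ]
    st <- status[i]
    beat_sd <- c(sbp = 4.1, map = 2.8, dbp = 2.3)
    beat_drift <- c(sbp = 0, map = 0, dbp = 0)
    ect_rate <- 0.02; ect_red <- 0.25
    if (st == "arrhythmia") { ect_rate <- 0.40; ect_red <- 0.50 }
    # unstable patients: slow hemodynamic drift pushing the beat-to-beat SD
    # of one component past its threshold (drift A adds ~A/sqrt(2) to SD)
    if (st == "stability_sbp") beat_drift[["sbp"]] <- 16
    if (st == "stability_map") beat_drift[["map"]] <- 10
    if (st == "stability_dbp") beat_drift[["dbp"]] <- 12

    shape <- beat_shape_params(sbp[i], dbp[i], map[i], hr[i],
                               rng_seed = seeds[3 * i - 2L])
    inv <- synth_aortic_waveform(shape, prof$duration, prof$sampling_rate,
                                 ectopic_rate = ect_rate,
                                 beat_sd = beat_sd, beat_drift = beat_drift,
                                 ectopic_pp_reduction = ect_red)
    if (st == "corrupt")
      inv$samples <- inv$samples - 90        # systematic zeroing error

    gt <- attr(inv, "ground_truth")$beats
    normal_beats <- gt[!gt$ectopic, , drop = FALSE]
    true_cbp <- c(sbp = mean(normal_beats$sbp),
                  map = mean(normal_beats$map),
                  dbp = mean(normal_beats$dbp))
    device_cbp <- c(sbp = true_cbp[["sbp"]] - err$sbp[i],
                    map = true_cbp[["map"]] - err$map[i],
                    dbp = true_cbp[["dbp"]] - err$dbp[i])

    cuff <- synth_cuff_recording(
      c(sbp[i], map[i], dbp[i]), heart_rate = hr[i],
      rng_seed = seeds[3 * i - 1L])
    flush <- synth_flush_test(
      flush_spec(fn_flush[i], z_flush[i]), rng_seed = seeds[3 * i])

    patients[[i]] <- list(
      patient_id = sprintf("P%03d", i), site = prof$site, status = st,
      invasive = inv, cuff = cuff, flush = flush,
      true_cbp = true_cbp, device_cbp = device_cbp, hr = hr[i])
  }

  manifest <- data.frame(
    patient_id = vapply(patients, `[[`, "", "patient_id"),
    site = vapply(patients, `[[`, "", "site"),
    status = status,
    true_sbp = vapply(patients, function(p) p$true_cbp[["sbp"]], 0),
    true_map = vapply(patients, function(p) p$true_cbp[["map"]], 0),
    true_dbp = vapply(patients, function(p) p$true_cbp[["dbp"]], 0),
    hr = hr)

  structure(list(spec = spec, patients = patients, manifest = manifest),
            class = "cbp_cohort")
}

#' @export
print.cbp_cohort <- function(x, ...) {
  cat(sprintf("<cbp_cohort> %d patients (%s)\n", length(x$patients),
              paste(sprintf("%s: %d", names(table(x$manifest$status)),
                            table(x$manifest$status)), collapse = ", ")))
  invisible(x)
}
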