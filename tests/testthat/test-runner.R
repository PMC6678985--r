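test_that("exclusion ledger reconciles the study-style accounting", {
  v <- data.frame(
    patient_id = sprintf("P%03d", 1:191),
    verdict = c(rep("exclude_stability", 14), rep("exclude_arrhythmia", 22),
                rep("exclude_corrupt", 10), rep("include", 145)),
    detail = c(rep("sd_sbp", 5), rep("sd_map", 3), rep("sd_dbp", 6),
               rep("", 177)))
  led <- exclusion_ledger(v)
  expect_equal(led$recorded, 191)
  expect_equal(led$analyzed, 145)
  tab <- setNames(led$table$count, led$table$reason)
  expect_equal(tab[["stability_sbp_sd"]], 5)
  expect_equal(tab[["stability_map_sd"]], 3)
  expect_equal(tab[["stability_dbp_sd"]], 6)
  expect_equal(tab[["arrhythmia"]], 22)
  expect_equal(tab[["corrupt"]], 10)
  # all included -> zero-count ledger
  v2 <- data.frame(patient_id = c("a", "b"), verdict = "include",
                   detail = "")
  expect_equal(sum(exclusion_ledger(v2)$table$count), 0)
  expect_error(exclusion_ledger(data.frame(patient_id = c("a", "a"),
                                           verdict = "include",
                                           detail = "")), "duplicate")
})

test_that("a full study run is deterministic and internally consistent", {
  co <- tiny_cohort(n = 8, seed = 21)
  cfg <- study_config()
  r1 <- run_study(co, cfg)
  r2 <- run_study(co, cfg)
  expect_identical(r1$agreement$SBP$mean_diff, r2$agreement$SBP$mean_diff)
  expect_identical(r1$pairs, r2$pairs)
  # ledger totals reconcile with report n
  expect_equal(r1$exclusions$analyzed + sum(r1$exclusions$table$count),
               r1$exclusions$recorded)
  expect_equal(r1$agreement$SBP$n, r1$exclusions$analyzed)
})

test_that("end-to-end equals manually chained module calls", {
  co <- tiny_cohort(n = 6, seed = 31)
  rep <- run_study(co, study_config())
  inv <- t(vapply(co$patients, function(p) {
    s <- analyze_invasive(p$invasive)$summary
    c(s$mean_sbp, s$mean_map, s$mean_dbp)
  }, numeric(3)))
  est <- t(vapply(co$patients, function(p)
    p$device_cbp[c("sbp", "map", "dbp")], numeric(3)))
  pairs <- paired_measurements(co$manifest$patient_id,
                               data.frame(sbp = inv[, 1], map = inv[, 2],
                                          dbp = inv[, 3]),
                               data.frame(sbp = est[, 1], map = est[, 2],
                                          dbp = est[, 3]))
  manual <- bland_altman(pairs, "SBP")
  expect_equal(manual$mean_diff, rep$agreement$SBP$mean_diff,
               tolerance = 1e-12)
  expect_equal(manual$sd_diff, rep$agreement$SBP$sd_diff, tolerance = 1e-12)
})

test_that("missing channels exclude the patient, never crash", {
  co <- tiny_cohort(n = 4, seed = 5)
  co$patients[[2]]$cuff <- NULL
  rep <- run_study(co, study_config())
  expect_equal(rep$exclusions$analyzed, 3)
  tab <- setNames(rep$exclusions$table$count, rep$exclusions$table$reason)
  expect_equal(tab[["incomplete"]], 1)
})

test_that("a single-patient study reports degenerate dispersion", {
  co <- tiny_cohort(n = 1, seed = 13)
  rep <- run_study(co, study_config())
  expect_true(rep$degenerate)
  expect_null(rep$agreement)
  expect_equal(rep$exclusions$analyzed, 1)
})

test_that("the oscillometric estimator path produces usable estimates", {
  co <- tiny_cohort(n = 5, seed = 77)
  rep <- run_study(co, study_config(estimator = "ratio_surrogate"))
  expect_equal(rep$exclusions$analyzed, 5)
  p <- rep$pairs
  expect_true(all(is.finite(p$est_map[p$included])))
  # surrogate MAP estimates track invasive MAP reasonably (calibration via
  # the cuff envelope, so only loose agreement is claimed)
  expect_lt(mean(abs(p$est_map[p$included] - p$inv_map[p$included])), 8)
})

test_that("study reports are written as JSON plus tidy CSVs", {
  co <- tiny_cohort(n = 4, seed = 3)
  out <- file.path(tempdir(), "study_out")
  rep <- run_study(co, study_config(), out_dir = out)
  expect_true(file.exists(file.path(out, "study_report.json")))
  expect_true(file.exists(file.path(out, "pairs.csv")))
  expect_true(file.exists(file.path(out, "plotdata_sbp.csv")))
  j <- jsonlite::read_json(file.path(out, "study_report.json"),
                           simplifyVector = TRUE)
  expect_equal(j$exclusions$analyzed, 4)
  expect_equal(j$agreement$SBP$mean_diff, rep$agreement$SBP$mean_diff,
               tolerance = 1e-9)
  pd <- read.csv(file.path(out, "plotdata_sbp.csv"))
  expect_equal(pd$difference, pd$invasive - pd$estimated)
  unlink(out, recursive = TRUE)
})

test_that("signals and cohorts round-trip through CSV + JSON sidecars", {
  w <- clean_aortic(duration = 6, fs = 240)
  path <- file.path(tempdir(), "sig.csv")
  write_signal(w, path, patient_id = "P001", site = "site_A")
  w2 <- read_signal(path)
  expect_equal(w2$samples, w$samples, tolerance = 1e-9)
  expect_equal(w2$sampling_rate, w$sampling_rate)
  expect_equal(w2$channel, "invasive")
  gt2 <- attr(w2, "ground_truth")
  expect_equal(gt2$beats$sbp, attr(w, "ground_truth")$beats$sbp,
               tolerance = 1e-9)
  file.remove(path, paste0(path, ".json"))

  co <- tiny_cohort(n = 3, seed = 55)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_equal(length(co2$patients), 3)
  expect_equal(co2$patients[[2]]$invasive$samples,
               co$patients[[2]]$invasive$samples, tolerance = 1e-9)
  expect_equal(co2$patients[[2]]$device_cbp, co$patients[[2]]$device_cbp,
               tolerance = 1e-9)
  r1 <- run_study(co, study_config())
  r2 <- run_study(co2, study_config())
  expect_equal(r1$agreement$SBP$mean_diff, r2$agreement$SBP$mean_diff,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("malformed signal files become itemized load errors", {
  co <- tiny_cohort(n = 2, seed = 66)
  dir <- file.path(tempdir(), "cohort_bad")
  write_cohort(co, dir)
  writeLines("garbage,not,a signal", file.path(dir, "P001_invasive.csv"))
  co2 <- read_cohort(dir)
  expect_true(any(grepl("P001", attr(co2, "load_errors"))))
  expect_null(co2$patients[[1]]$invasive)
  rep <- run_study(co2, study_config())
  tab <- setNames(rep$exclusions$table$count, rep$exclusions$table$reason)
  expect_equal(tab[["incomplete"]], 1)
  expect_equal(rep$exclusions$analyzed, 1)
  unlink(dir, recursive = TRUE)
})

test_that("study config validates estimators and thresholds", {
  expect_error(study_config(estimator = "no_such"), "unknown estimator")
  expect_error(study_config(sd_limits = c(sbp = -1, map = 6, dbp = 6)))
})
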