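test_that("pulsatile separation is an exact decomposition of the raw", {
  w <- synth_cuff_recording(c(150, 107, 85), 69, rng_seed = 4)
  rec <- separate_pulsatile(w)
  expect_equal(rec$ramp + rec$pulsatile, w$samples[rec$segment],
               tolerance = 1e-9)
  expect_equal(rec$deflation_rate, 4, tolerance = 0.1)
  expect_lt(abs(mean(rec$pulsatile)), 0.2)
})

test_that("a pulse-free ramp gives near-zero pulsatile and errors downstream", {
  n <- 3001
  x <- 180 - 4 * (0:(n - 1)) / 100
  w <- pressure_waveform(x, 100, channel = "cuff")
  rec <- separate_pulsatile(w)
  expect_lt(max(abs(rec$pulsatile)), 1e-6)
  expect_error(find_pulses(rec), "too few pulses")
  # no deflation at all
  expect_error(separate_pulsatile(
    pressure_waveform(rep(120, 500), 100, channel = "cuff")),
    "deflation")
})

test_that("pulse count is consistent with heart rate x duration", {
  w <- synth_cuff_recording(c(140, 100, 80), 69, start_pressure = 180,
                            end_pressure = 40, rng_seed = 6)
  rec <- find_pulses(separate_pulsatile(w))
  # 69/60 * 35 s of deflation = ~40 cycles; allow the edge cycles
  expect_equal(nrow(rec$pulses), 40, tolerance = 3)
  expect_true(all(diff(rec$pulses$foot) > 0))
  expect_true(all(rec$pulses$amplitude >= 0.1))
})

test_that("detected feet align with the generator's cuff ground truth", {
  w <- synth_cuff_recording(c(150, 107, 85), 69, rng_seed = 8)
  rec <- find_pulses(separate_pulsatile(w))
  gt_feet <- attr(w, "ground_truth")$feet
  gt_t <- (gt_feet - 1) / w$sampling_rate
  det <- rec$pulses$t_foot[rec$pulses$detected]
  matched <- vapply(det, function(tf) min(abs(gt_t - tf)), numeric(1))
  # feet within 30 ms of ground truth for the central (detected) pulses
  expect_lt(median(matched), 0.03)
})

test_that("envelope MAP lands at true MAP across random recordings", {
  set.seed(42)
  errs <- numeric(0)
  for (i in 1:40) {
    map <- runif(1, 70, 140); pp <- runif(1, 35, 70)
    dbp <- map - 0.4 * pp; sbp <- dbp + pp
    hr <- runif(1, 50, 110)
    w <- synth_cuff_recording(c(sbp, map, dbp), hr, rng_seed = i)
    b <- envelope_bp(find_pulses(separate_pulsatile(w)))
    errs <- c(errs, b$map - map)
    expect_true(b$dbp < b$map && b$map < b$sbp)
  }
  expect_lt(max(abs(errs)), 2)
})

test_that("a symmetric envelope gives ratio pressures equidistant from MAP", {
  cuff <- seq(160, 40, by = -4)
  amp <- pmax(0.05, 3 * (1 - abs(cuff - 100) / 50))
  rec <- structure(list(
    pulses = data.frame(foot = seq_along(cuff), t_foot = seq_along(cuff),
                        cuff = cuff, amplitude = amp, detected = TRUE)),
    class = "oscillometric_recording")
  b <- envelope_bp(rec, systolic_ratio = 0.5, diastolic_ratio = 0.5)
  expect_equal(b$map, 100, tolerance = 1)
  expect_equal(b$sbp - b$map, b$map - b$dbp, tolerance = 1.5)
})

test_that("monotone envelopes are rejected (MAP not bracketed)", {
  cuff <- seq(160, 60, by = -4)
  amp <- seq(0.2, 3, length.out = length(cuff))   # still rising at the end
  rec <- structure(list(
    pulses = data.frame(foot = seq_along(cuff), t_foot = seq_along(cuff),
                        cuff = cuff, amplitude = amp, detected = TRUE)),
    class = "oscillometric_recording")
  expect_error(envelope_bp(rec), "bracket")
})

test_that("residuum flags step artifacts but not clean recordings", {
  w <- synth_cuff_recording(c(150, 107, 85), 69, rng_seed = 5)
  rs0 <- residuum_score(separate_pulsatile(w))
  expect_equal(sum(rs0$windows$flagged), 0)
  expect_false(rs0$recording_flag)
  # inject a 5 mmHg step halfway through
  w2 <- w
  half <- floor(length(w2$samples) / 2)
  w2$samples[half:length(w2$samples)] <- w2$samples[half:length(w2$samples)] + 5
  rs1 <- residuum_score(separate_pulsatile(w2))
  step_t <- (half - 1) / w$sampling_rate
  hit <- rs1$windows$flagged[abs(rs1$windows$t_start +
                                   1 - step_t) <= 2.5]
  expect_true(any(hit))
  # corrupting over a third of the windows sets the recording-level flag
  w3 <- w
  set.seed(1)
  n3 <- length(w3$samples)
  idx <- seq_len(round(0.4 * n3))
  w3$samples[idx] <- w3$samples[idx] + rnorm(length(idx), 0, 4)
  rs2 <- residuum_score(separate_pulsatile(w3))
  expect_true(rs2$recording_flag)
})

test_that("central estimation calibrates to brachial MAP and DBP", {
  w <- synth_cuff_recording(c(150, 107, 85), 69, rng_seed = 3)
  rec <- find_pulses(separate_pulsatile(w))
  b <- envelope_bp(rec)
  ce <- estimate_central(rec, b, alpha = 0.8)
  # calibration contract
  cal <- ce$ensemble
  tm <- (sum(cal) - 0.5 * (cal[1] + cal[length(cal)])) / (length(cal) - 1)
  expect_equal(tm, b$map, tolerance = 0.01)
  expect_equal(min(cal), b$dbp, tolerance = 1e-6)
  # surrogate formula: csbp = map + alpha * (pulse max - map)
  expect_equal(ce$csbp, b$map + 0.8 * (max(cal) - b$map), tolerance = 1e-9)
  expect_equal(ce$cmap, b$map)
  expect_equal(ce$cdbp, b$dbp)
  # alpha = 1: csbp equals the calibrated pulse peak
  ce1 <- estimate_central(rec, b, alpha = 1)
  expect_equal(ce1$csbp, max(ce1$ensemble), tolerance = 1e-9)
})

test_that("central estimate is invariant to a constant pressure offset", {
  w <- synth_cuff_recording(c(150, 107, 85), 69, rng_seed = 12)
  w2 <- w; w2$samples <- w2$samples + 25    # shifted ramp start pressure
  r1 <- analyze_oscillometric(w)
  r2 <- analyze_oscillometric(w2)
  expect_equal(r2$brachial$map - r1$brachial$map, 25, tolerance = 0.75)
  expect_equal(r2$central$csbp - r2$central$cmap,
               r1$central$csbp - r1$central$cmap, tolerance = 0.5)
})

test_that("estimator registry enforces the contract", {
  expect_true("ratio_surrogate" %in% list_estimators())
  register_estimator("bad", function(cal, brachial, ...)
    list(csbp = 50, cmap = 100, cdbp = 110))
  w <- synth_cuff_recording(c(150, 107, 85), 69, rng_seed = 3)
  rec <- find_pulses(separate_pulsatile(w))
  b <- envelope_bp(rec)
  expect_error(estimate_central(rec, b, estimator = "bad"), "inconsistent")
  expect_error(estimate_central(rec, b, estimator = "nonexistent"),
               "unknown estimator")
})
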