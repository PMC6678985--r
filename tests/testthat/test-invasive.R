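test_that("beat values are exact on analytic beats", {
  # square beat: 120 for the first half, 80 for the second -> (120, 80, 100)
  w <- square_beat_waveform()
  b <- beat_values(w, data.frame(start = 1L, end = 101L))
  expect_equal(b$sbp, 120)
  expect_equal(b$dbp, 80)
  expect_equal(b$map, 100, tolerance = 0.5)   # trapezoid edge weighting
  # constant beat
  wc <- pressure_waveform(rep(100, 50), 100, channel = "invasive")
  bc <- beat_values(wc, data.frame(start = 1L, end = 50L))
  expect_equal(c(bc$sbp, bc$dbp, bc$map), c(100, 100, 100))
  expect_error(beat_values(wc, data.frame(start = 1L, end = 80L)),
               "outside waveform")
})

test_that("beat_values matches an independent brute-force scan", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(50:400, 1)
    x <- 80 + cumsum(rnorm(n))
    w <- pressure_waveform(x, 250, channel = "invasive")
    ends <- sort(sample(5:(n - 1), 3))
    beats <- data.frame(start = c(1L, ends[1], ends[2]),
                        end = c(ends[1], ends[2], ends[3]))
    b <- beat_values(w, beats)
    for (i in 1:3) {
      seg_open <- x[beats$start[i]:(beats$end[i] - 1)]
      # independent oracle: explicit loop max/min + pracma trapezoid
      mx <- -Inf; mn <- Inf
      for (v in seg_open) { if (v > mx) mx <- v; if (v < mn) mn <- v }
      seg_closed <- x[beats$start[i]:beats$end[i]]
      tt <- seq_along(seg_closed) / 250
      expect_identical(b$sbp[i], mx)
      expect_identical(b$dbp[i], mn)
      expect_equal(b$map[i],
                   pracma::trapz(tt, seg_closed) / (tt[length(tt)] - tt[1]))
    }
  }
})

test_that("beat detection finds whole beats and accurate feet", {
  w <- clean_aortic(hr = 60, duration = 20)
  beats <- detect_beats(w)
  expect_true(nrow(beats) %in% c(19, 20))
  # feet within 20 ms of the generator's ground truth
  gt <- attr(w, "ground_truth")$beats
  for (tf in beats$t_foot) {
    expect_lt(min(abs(gt$t_foot - tf)), 0.020)
  }
  expect_error(
    detect_beats(pressure_waveform(rep(100, 1000), 240,
                                   channel = "invasive")),
    "no beats")
  expect_error(detect_beats(synth_cuff_recording(c(120, 93, 75), 60)),
               "invasive channel")
})

test_that("outlier clearing follows the median/robust-SD rule", {
  mk <- function(sbp, dbp = rep(80, length(sbp)),
                 dur = rep(1, length(sbp))) {
    data.frame(start = 1, end = 2, sbp = sbp, dbp = dbp, map = (sbp + dbp) / 2,
               duration_s = dur, kept = TRUE, exclusion_reason = "none")
  }
  # 100 identical beats + 2 with SBP 40 mmHg lower -> exactly 2 cleared
  b <- clear_outlier_beats(mk(c(rep(120, 100), 80, 80)))
  expect_equal(sum(!b$kept), 2)
  expect_setequal(which(!b$kept), c(101, 102))
  # all identical -> none cleared
  expect_true(all(clear_outlier_beats(mk(rep(120, 10)))$kept))
  # {120 x 9, 121}: deviation 1 mmHg is below the 1 mmHg-floored rule
  expect_true(all(clear_outlier_beats(mk(c(rep(120, 9), 121)))$kept))
  # idempotent
  b2 <- clear_outlier_beats(b)
  expect_identical(b$kept, b2$kept)
  # shortened cycles are cleared as extrasystoles
  b3 <- clear_outlier_beats(mk(rep(120, 10), dur = c(rep(1, 9), 0.6)))
  expect_equal(which(!b3$kept), 10L)
  expect_error(clear_outlier_beats(mk(c(120, 121))), "at least 3")
})

test_that("recording summary uses kept beats and n-1 SDs", {
  b <- data.frame(sbp = c(140, 150, 60), dbp = c(80, 82, 30),
                  map = c(100, 104, 40), kept = c(TRUE, TRUE, FALSE))
  s <- summarize_recording(b)
  expect_equal(s$mean_sbp, 145)
  expect_equal(s$sd_sbp, sd(c(140, 150)))   # 7.071
  expect_equal(s$n_beats_total, 3L)
  expect_equal(s$excluded_fraction, 1 / 3)
  # single kept beat: SDs are zero by convention
  s1 <- summarize_recording(data.frame(sbp = 120, dbp = 80, map = 95,
                                       kept = TRUE))
  expect_equal(s1$sd_sbp, 0)
  expect_error(summarize_recording(data.frame(sbp = 1, dbp = 1, map = 1,
                                              kept = FALSE)), "zero kept")
})

test_that("exclusion rules use strict thresholds, arrhythmia first", {
  mk_sum <- function(sd_sbp = 1, sd_map = 1, sd_dbp = 1, frac = 0) {
    structure(list(mean_sbp = 120, mean_dbp = 80, mean_map = 95,
                   sd_sbp = sd_sbp, sd_dbp = sd_dbp, sd_map = sd_map,
                   n_beats_total = 100L,
                   n_beats_excluded = as.integer(100 * frac),
                   excluded_fraction = frac),
              class = "recording_summary")
  }
  expect_equal(apply_exclusion_rules(mk_sum(sd_sbp = 10.1))$verdict,
               "exclude_stability")
  # study-mean SDs at the 30% boundary: boundary not exceeded -> include
  expect_equal(apply_exclusion_rules(
    mk_sum(sd_sbp = 4.08, sd_map = 2.83, sd_dbp = 2.31, frac = 0.30))$verdict,
    "include")
  expect_equal(apply_exclusion_rules(mk_sum(frac = 0.31))$verdict,
               "exclude_arrhythmia")
  # exactly at the SD thresholds -> include (strict "more than")
  expect_equal(apply_exclusion_rules(
    mk_sum(sd_sbp = 10, sd_map = 6, sd_dbp = 6))$verdict, "include")
  # arrhythmia takes precedence over stability
  expect_equal(apply_exclusion_rules(
    mk_sum(sd_sbp = 12, frac = 0.4))$verdict, "exclude_arrhythmia")
  # stability sub-reason attribution order: SBP before MAP before DBP
  expect_equal(apply_exclusion_rules(
    mk_sum(sd_sbp = 11, sd_dbp = 7))$detail, "sd_sbp")
  expect_equal(apply_exclusion_rules(
    mk_sum(sd_map = 7, sd_dbp = 7))$detail, "sd_map")
})

test_that("round trip recovers the generator's beats at several shapes", {
  grid <- list(c(145.1, 72.1, 101.5, 69), c(120, 80, 100, 60),
               c(180, 95, 125, 95), c(100, 60, 76, 50))
  for (g in grid) {
    w <- clean_aortic(g[1], g[2], g[3], g[4], duration = 15, fs = 500)
    a <- analyze_invasive(w)
    expect_equal(a$summary$mean_sbp, g[1], tolerance = 0.5)
    expect_equal(a$summary$mean_dbp, g[2], tolerance = 0.5)
    expect_equal(a$summary$mean_map, g[3], tolerance = 1)
    expect_equal(a$verdict, "include")
  }
})

test_that("per-beat MAP is robust to resampling across the site rates", {
  sh <- beat_shape_params(145.1, 72.1, 101.5, 69, rng_seed = 2)
  w <- synth_aortic_waveform(sh, 20, 2000, noise_sd = 0.2)
  w240 <- resample_waveform(w, 240)
  a1 <- analyze_invasive(w)
  a2 <- analyze_invasive(w240)
  expect_lt(abs(a1$summary$mean_map - a2$summary$mean_map), 0.5)
})
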