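#' Beat shape parameters for the aortic waveform generator
#'
#' Target pressures and rate for a synthetic aortic beat train. The beat
#' morphology is a piecewise analytic pulse: a raised-cosine systolic upstroke
#' over a fixed fraction of the cycle, followed by an exponential diastolic
#' decay with an optional dicrotic notch. The decay-rate parameter is solved
#' numerically per beat so that the beat's time-average hits `map_target`,
#' which gives analytic ground truth for all three per-beat values.
#'
#' @param sbp Target systolic pressure, mmHg.
#' @param dbp Target diastolic pressure, mmHg.
#' @param map_target Target mean arterial pressure, mmHg; must lie strictly
#'   between `dbp` and `sbp` (and within the morphologically feasible band,
#'   roughly 0.17-0.82 of pulse pressure above `dbp`).
#' @param heart_rate Heart rate, beats/min, in \[30, 180\].
#' @param notch_depth Dicrotic notch depth as a fraction of the local pulse
#'   height, in \[0, 0.5\]. Default 0.1.
#' @param rng_seed Integer seed; all randomness in generation flows from it.
#'
#' @return A `beat_shape_params` list.
#' @export
beat_shape_params <- function(sbp, dbp, map_target, heart_rate,
                              notch_depth = 0.1, rng_seed = 1L) {
  if (!(dbp < map_target && map_target < sbp))
    stop("require dbp < map_target < sbp", call. = FALSE)
  if (heart_rate < 30 || heart_rate > 180)
    stop("heart_rate must lie in [30, 180] beats/min", call. = FALSE)
  if (notch_depth < 0 || notch_depth > 0.5)
    stop("notch_depth must lie in [0, 0.5]", call. = FALSE)
  structure(list(sbp = sbp, dbp = dbp, map_target = map_target,
                 heart_rate = heart_rate, notch_depth = notch_depth,
                 rng_seed = as.integer(rng_seed)),
            class = "beat_shape_params")
}

# Normalized beat shape w(u) on u in [0, 1): raised-cosine upstroke over
# [0, a], exponential decay with rate k over (a, 1], multiplicative dicrotic
# notch on the early decay. w(0) = w(1) = 0, max(w) = 1 at u = a.
beat_shape <- function(u, k, a = 0.3, notch_depth = 0) {
  w <- numeric(length(u))
  up <- u <= a
  w[up] <- 0.5 * (1 - cos(pi * u[up] / a))
  v <- (u[!up] - a) / (1 - a)
  if (abs(k) < 1e-8) {
    dec <- 1 - v
  } else {
    dec <- (exp(-k * v) - exp(-k)) / (1 - exp(-k))
  }
  if (notch_depth > 0) {
    v0 <- 0.05; vw <- 0.30
    inn <- v >= v0 & v <= v0 + vw
    dec[inn] <- dec[inn] * (1 - notch_depth * sin(pi * (v[inn] - v0) / vw)^2)
  }
  w[!up] <- dec
  w
}

# Trapezoidal mean of the shape over the closed beat [0, 1] sampled at
# u = j/n (the same quadrature beat_values uses). Endpoints are 0.
beat_shape_mean <- function(k, n, a = 0.3, notch_depth = 0) {
  u <- seq_len(n - 1L) / n
  sum(beat_shape(u, k, a, notch_depth)) / n
}

# Solve the decay rate k so the sampled beat mean equals m_frac (the MAP
# position as a fraction of pulse pressure). Errors if morphologically
# infeasible.
solve_beat_decay <- function(m_frac, n, a = 0.3, notch_depth = 0,
                             k_range = c(-40, 40), clamp = FALSE) {
  lo <- beat_shape_mean(k_range[2], n, a, notch_depth)  # smallest mean
  hi <- beat_shape_mean(k_range[1], n, a, notch_depth)  # largest mean
  if (m_frac <= lo || m_frac >= hi) {
    if (!clamp)
      stop(sprintf(paste0("infeasible morphology: MAP fraction %.3f outside ",
                          "achievable (%.3f, %.3f); map_target too close to ",
                          "dbp or sbp"), m_frac, lo, hi), call. = FALSE)
    m_frac <- min(max(m_frac, lo + 1e-3), hi - 1e-3)
  }
  stats::uniroot(function(k) beat_shape_mean(k, n, a, notch_depth) - m_frac,
                 interval = k_range, tol = 1e-10)$root
}

#' Synthesize an invasive aortic pressure waveform with ground truth
#'
#' Builds a beat train from per-beat targets drawn around the shape
#' parameters, with controllable beat-to-beat variability, ectopic
#' (extrasystolic) beats and additive measurement noise. Ectopic beats have a
#' shortened preceding interval and a reduced pulse pressure; their count is
#' fixed at `round(ectopic_rate * n_beats)` and they are placed at evenly
#' spaced beat positions, so the contamination level of a recording is exact
#' and reproducible.
#'
#' The returned ground-truth table holds, per beat, both the generator's
#' target values and the realized values (max, min, trapezoidal time-average)
#' of the emitted samples over the true beat interval, so downstream beat
#' analysis can be checked beat-for-beat.
#'
#' @param shape A [beat_shape_params()] object.
#' @param duration Recording length, seconds (>= 2 beats).
#' @param sampling_rate Sampling rate, Hz (>= 100; the study systems used
#'   240, 500 and 2000 Hz).
#' @param ectopic_rate Fraction of beats that are ectopic, in \[0, 1\].
#' @param beat_sd Named numeric: per-beat standard deviations of the SBP, MAP
#'   and DBP targets in mmHg. Defaults `c(sbp = 4.1, map = 2.8, dbp = 2.3)`,
#'   the within-recording variability observed in catheter-lab recordings of
#'   hemodynamically stable patients.
#' @param beat_drift Named numeric (`sbp`, `map`, `dbp`): amplitude in mmHg
#'   of a slow sinusoidal drift (two cycles per recording) added to the
#'   per-beat targets, emulating hemodynamic instability. A drift of
#'   amplitude A contributes close to A/sqrt(2) to the beat-to-beat SD.
#'   Default zero.
#' @param hr_cv Coefficient of variation of the beat period (default 0.03).
#' @param noise_sd SD of additive white measurement noise, mmHg (default 0.5).
#' @param ectopic_pp_reduction Fractional pulse-pressure reduction of ectopic
#'   beats (default 0.25).
#' @param ectopic_interval_factor Preceding-interval shortening factor for
#'   ectopic beats (default 0.6).
#'
#' @return A `pressure_waveform` (channel `"invasive"`) whose
#'   `"ground_truth"` attribute holds `beats` (data.frame: `beat`, `t_foot`,
#'   `start`, `end` half-open sample indices, `sbp`, `dbp`, `map` realized,
#'   `target_sbp`, `target_dbp`, `target_map`, `ectopic`) and `shape`.
#' @export
synth_aortic_waveform <- function(shape, duration, sampling_rate,
                                  ectopic_rate = 0,
                                  beat_sd = c(sbp = 4.1, map = 2.8, dbp = 2.3),
                                  beat_drift = c(sbp = 0, map = 0, dbp = 0),
                                  hr_cv = 0.03, noise_sd = 0.5,
                                  ectopic_pp_reduction = 0.25,
                                  ectopic_interval_factor = 0.6) {
  stopifnot(inherits(shape, "beat_shape_params"))
  if (sampling_rate < 100)
    stop("sampling_rate must be >= 100 Hz", call. = FALSE)
  period <- 60 / shape$heart_rate
  if (duration < 2 * period)
    stop("duration must cover at least 2 beats", call. = FALSE)
  if (ectopic_rate < 0 || ectopic_rate > 1)
    stop("ectopic_rate must lie in [0, 1]", call. = FALSE)
  pp <- shape$sbp - shape$dbp
  m_frac0 <- (shape$map_target - shape$dbp) / pp
  # feasibility check on the nominal beat before any jitter
  n0 <- max(10L, round(period * sampling_rate))
  solve_beat_decay(m_frac0, n0, notch_depth = shape$notch_depth)

  set.seed(shape$rng_seed)
  n_beats <- floor(duration / period)
  periods <- period * (1 + hr_cv * stats::rnorm(n_beats))
  periods <- pmax(periods, 60 / 180)

  ectopic <- rep(FALSE, n_beats)
  n_ect <- round(ectopic_rate * n_beats)
  if (n_ect > 0) {
    idx <- unique(round(seq(2, max(2, n_beats - 1), length.out = n_ect)))
    ectopic[idx] <- TRUE
  }
  periods[ectopic] <- periods[ectopic] * ectopic_interval_factor

  # per-beat targets; foot pressures are shared between adjacent beats so the
  # assembled signal is continuous
  drift <- function(amp, m) amp * sin(2 * pi * 2 * seq_len(m) / n_beats)
  foot_p <- shape$dbp + beat_sd[["dbp"]] * stats::rnorm(n_beats + 1L) +
    drift(beat_drift[["dbp"]], n_beats + 1L)
  sbp_t <- shape$sbp + beat_sd[["sbp"]] * stats::rnorm(n_beats) +
    drift(beat_drift[["sbp"]], n_beats)
  map_t <- shape$map_target + beat_sd[["map"]] * stats::rnorm(n_beats) +
    drift(beat_drift[["map"]], n_beats)
  red <- ifelse(ectopic, 1 - ectopic_pp_reduction, 1)

  n_i <- pmax(10L, round(periods * sampling_rate))
  start_idx <- cumsum(c(1L, n_i[-n_beats]))
  total_n <- sum(n_i) + 1L
  samples <- numeric(total_n)

  gt <- data.frame(beat = seq_len(n_beats), t_foot = NA_real_,
                   start = start_idx, end = start_idx + n_i,
                   sbp = NA_real_, dbp = NA_real_, map = NA_real_,
                   target_sbp = NA_real_, target_dbp = NA_real_,
                   target_map = NA_real_, ectopic = ectopic)

  for (i in seq_len(n_beats)) {
    n <- n_i[i]
    u <- (0:(n - 1L)) / n
    f0 <- foot_p[i]; f1 <- foot_p[i + 1L]
    a <- 0.3
    # the foot-to-foot baseline shift completes during systole, so diastole
    # decays monotonically to the next foot (no spurious interior minima)
    base <- f0 + (f1 - f0) * pmin(u / a, 1)
    mean_base <- (sum(base) + 0.5 * (f1 - f0)) / n   # closed-trapezoid mean
    pp_i <- (sbp_t[i] - f1) * red[i]
    pp_i <- max(pp_i, 10)                       # floor: keep a real pulse
    map_i <- mean_base + (map_t[i] - mean_base) * red[i]  # ectopics: MAP drops
    m_frac <- (map_i - mean_base) / pp_i
    k <- solve_beat_decay(m_frac, n, a = a, notch_depth = shape$notch_depth,
                          clamp = TRUE)
    w <- beat_shape(u, k, a = a, notch_depth = shape$notch_depth)
    seg <- base + pp_i * w
    samples[start_idx[i]:(start_idx[i] + n - 1L)] <- seg
    # targets = noise-free per-beat extrema of the emitted (half-open) beat
    gt$target_sbp[i] <- max(seg)
    gt$target_dbp[i] <- min(seg)
    gt$target_map[i] <- mean_base + pp_i * beat_shape_mean(
      k, n, a = a, notch_depth = shape$notch_depth)
    gt$t_foot[i] <- (start_idx[i] - 1L) / sampling_rate
  }
  samples[total_n] <- foot_p[n_beats + 1L]

  if (noise_sd > 0)
    samples <- samples + noise_sd * stats::rnorm(total_n)

  # realized per-beat values on the emitted samples, closed-interval trapezoid
  for (i in seq_len(n_beats)) {
    s <- gt$start[i]; e <- gt$end[i]
    seg <- samples[s:e]
    gt$sbp[i] <- max(seg[-length(seg)])
    gt$dbp[i] <- min(seg[-length(seg)])
    gt$map[i] <- trapz_mean(seg)
  }

  pressure_waveform(samples, sampling_rate, channel = "invasive",
                    ground_truth = list(beats = gt, shape = shape,
                                        noise_sd = noise_sd))
}

# trapezoidal time-average of a closed segment (uniform spacing)
trapz_mean <- function(seg) {
  n <- length(seg)
  (sum(seg) - 0.5 * (seg[1] + seg[n])) / (n - 1L)
}
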