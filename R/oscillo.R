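#' @title Oscillometric cuff-deflation processing
#' @description Separates the pulsatile component from the deflating cuff
#'   pressure, identifies single pulse waves and their foot points, builds
#'   the amplitude envelope, derives brachial values from characteristic
#'   ratios, scores artifacts via the residuum (the spread between the
#'   actual and the expected deflating cuff pressure), and feeds an
#'   ensemble-averaged, MAP/DBP-calibrated pulse into a pluggable
#'   central-pressure estimator.
#' @name oscillometric-processing
NULL

#' Separate the pulsatile component from the cuff pressure
#'
#' Finds the monotone deflation segment, fits a robust (Huber M-estimator)
#' line to it, recentred so the residuals average zero, and splits the raw
#' signal into `ramp + pulsatile`.
#'
#' @param raw A `pressure_waveform` with channel `"cuff"`.
#' @param min_span Minimum pressure span of the deflation segment, mmHg
#'   (default 60).
#' @return An `oscillometric_recording`: `raw`, `segment` (index range),
#'   `time` (s, within segment), `ramp`, `pulsatile`, `deflation_rate`
#'   (mmHg/s).
#' @export
separate_pulsatile <- function(raw, min_span = 60) {
  stopifnot(inherits(raw, "pressure_waveform"))
  if (raw$channel != "cuff")
    stop("separate_pulsatile expects a cuff channel", call. = FALSE)
  x <- raw$samples
  fs <- raw$sampling_rate
  n <- length(x)
  win <- max(1L, round(fs))
  sm <- as.numeric(stats::filter(x, rep(1 / win, win), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  ds <- c(diff(sm), 0) * fs
  defl <- ds < -0.5
  # close momentary interruptions (< 2 s) caused by pulse ripple
  r0 <- rle(defl)
  if (length(r0$lengths) > 2L) {
    inner <- seq(2L, length(r0$lengths) - 1L)
    r0$values[inner][!r0$values[inner] & r0$lengths[inner] < 2 * fs] <- TRUE
  }
  defl <- inverse.rle(r0)
  r <- rle(defl)
  if (!any(r$values))
    stop("no monotone deflation segment found", call. = FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  seg <- starts[best]:ends[best]
  if (abs(sm[seg[1]] - sm[seg[length(seg)]]) < min_span)
    stop("no monotone deflation segment spanning >= ", min_span, " mmHg",
         call. = FALSE)
  tt <- (seg - 1L) / fs
  # a pulse-free (zero-residual) segment makes the IRLS scale degenerate;
  # the returned fit is still exact, so the convergence warning is moot
  fit <- suppressWarnings(MASS::rlm(x[seg] ~ tt, maxit = 50))
  ramp <- as.numeric(stats::fitted(fit))
  resid <- x[seg] - ramp
  ramp <- ramp + mean(resid)               # residuals average exactly zero
  pulsatile <- x[seg] - ramp
  structure(list(raw = raw, segment = seg, time = tt, ramp = ramp,
                 pulsatile = pulsatile,
                 deflation_rate = -unname(stats::coef(fit)[2])),
            class = "oscillometric_recording")
}

#' @export
print.oscillometric_recording <- function(x, ...) {
  cat(sprintf("<oscillometric_recording> %d samples, deflation %.2f mmHg/s, cuff %.0f-%.0f mmHg\n",
              length(x$pulsatile), x$deflation_rate,
              max(x$ramp), min(x$ramp)))
  invisible(x)
}

#' Identify pulses and foot points in the pulsatile signal
#'
#' Foot points (diastolic minimum before each upstroke) are detected on a
#' narrow lowpass-filtered copy of the pulsatile component; the foot grid is
#' then continued periodically (at the median beat interval) into the
#' low-amplitude flanks of the deflation, where individual pulses are too
#' small to trigger detection but their residual amplitude still anchors the
#' envelope's noise floor. Each pulse is the half-open interval between
#' consecutive feet, with amplitude max - min and the cuff pressure read off
#' the fitted ramp at the foot. Pulses below the minimum amplitude floor are
#' discarded.
#'
#' @param rec An `oscillometric_recording` from [separate_pulsatile()].
#' @param min_amplitude Amplitude floor in mmHg (default 0.1).
#' @param slope_frac Upstroke threshold as fraction of peak slope
#'   (default 0.3).
#' @return `rec` with added `pulses` data.frame (`foot` segment-local index,
#'   `t_foot` s, `cuff` mmHg, `amplitude` mmHg, `detected` logical: FALSE
#'   for grid-continued cycles), `detection` (the narrow-band signal the
#'   feet and amplitudes were measured on) and `filtered` (a wider-band
#'   version retaining pulse morphology, used for the ensemble pulse).
#' @export
find_pulses <- function(rec, min_amplitude = 0.1, slope_frac = 0.3) {
  stopifnot(inherits(rec, "oscillometric_recording"))
  fs <- rec$raw$sampling_rate
  p <- rec$pulsatile
  # narrow band for detection/amplitudes, wider band for morphology
  pf <- filt_zp(p, fs, min(3, 0.225 * fs))
  pm <- filt_zp(p, fs, min(10, 0.45 * fs))
  feet <- tryCatch(
    detect_feet(pf, fs, slope_frac = slope_frac, refractory = 0.25,
                min_range = 0.3),
    error = function(e) stop("too few pulses for envelope: ",
                             conditionMessage(e), call. = FALSE))
  if (length(feet) < 6L)
    stop("too few pulses for envelope", call. = FALSE)
  detected <- rep(TRUE, length(feet))

  # periodic continuation of the foot grid across the whole segment
  m <- round(stats::median(diff(feet)))
  n <- length(pf)
  while (feet[1] - m >= 1L) {
    feet <- c(feet[1] - m, feet); detected <- c(FALSE, detected)
  }
  while (feet[length(feet)] + m <= n) {
    feet <- c(feet, feet[length(feet)] + m); detected <- c(detected, FALSE)
  }
  gaps <- which(diff(feet) > 1.5 * m)
  if (length(gaps) > 0) {
    add <- unlist(lapply(gaps, function(g) {
      k <- round((feet[g + 1L] - feet[g]) / m) - 1L
      if (k > 0) feet[g] + seq_len(k) * m else integer(0)
    }))
    feet <- c(feet, add); detected <- c(detected, rep(FALSE, length(add)))
    o <- order(feet); feet <- feet[o]; detected <- detected[o]
  }

  k <- length(feet) - 1L
  amp <- vapply(seq_len(k), function(i) {
    seg <- pf[feet[i]:(feet[i + 1L] - 1L)]
    max(seg) - min(seg)
  }, numeric(1))
  pulses <- data.frame(foot = feet[-length(feet)],
                       t_foot = rec$time[feet[-length(feet)]],
                       cuff = rec$ramp[feet[-length(feet)]],
                       amplitude = amp,
                       detected = detected[-length(detected)])
  pulses <- pulses[pulses$amplitude >= min_amplitude, , drop = FALSE]
  if (sum(pulses$detected) < 5L)
    stop("too few pulses for envelope", call. = FALSE)
  rownames(pulses) <- NULL
  rec$pulses <- pulses
  rec$detection <- pf
  rec$filtered <- pm
  rec
}

#' Brachial pressures from the oscillometric envelope
#'
#' MAP is the cuff pressure at the maximum of the smoothed amplitude
#' envelope (moving average over 5 pulses, quadratic peak refinement);
#' systolic and diastolic pressures are where the envelope falls to the
#' characteristic ratios of the peak amplitude on the high- and low-pressure
#' side respectively, linearly interpolated between envelope points.
#'
#' @param rec An `oscillometric_recording` after [find_pulses()].
#' @param systolic_ratio,diastolic_ratio Characteristic ratios
#'   (defaults 0.55 and 0.70, mid-range of published oscillometric
#'   practice; the validation layer does not depend on them).
#' @param smooth_window Envelope moving-average window, pulses (default 5).
#' @return A `brachial_estimate`: `sbp`, `map`, `dbp`, `method`,
#'   `systolic_ratio`, `diastolic_ratio`, `envelope` (data.frame `cuff`,
#'   `amplitude`, `smoothed`).
#' @export
envelope_bp <- function(rec, systolic_ratio = 0.55, diastolic_ratio = 0.70,
                        smooth_window = 5) {
  stopifnot(inherits(rec, "oscillometric_recording"))
  if (is.null(rec$pulses)) stop("run find_pulses() first", call. = FALSE)
  pu <- rec$pulses[order(rec$pulses$t_foot), , drop = FALSE]
  a <- pu$amplitude
  ks <- smooth_window
  sm <- as.numeric(stats::filter(a, rep(1 / ks, ks), sides = 2))
  # shrink the window at the edges instead of dropping pulses
  for (i in which(is.na(sm))) {
    h <- min(i - 1L, length(a) - i, ks %/% 2)
    sm[i] <- mean(a[(i - h):(i + h)])
  }
  imax <- which.max(sm)
  if (imax <= 1L || imax >= length(sm))
    stop("cuff range did not bracket MAP (envelope maximum at boundary)",
         call. = FALSE)
  # envelope peak: Gaussian-with-floor model fitted to the smoothed
  # envelope. The floor absorbs the constant noise inflation of the
  # max-min amplitudes; the Gaussian centre is the MAP estimate. Falls back
  # to an amplitude-weighted log-quadratic fit, then to the raw maximum.
  pc <- pu$cuff
  map <- NA_real_; amax <- sm[imax]
  df <- data.frame(p = pc, a = sm)
  fit <- tryCatch(suppressWarnings(stats::nls(
    a ~ c0 + A * exp(-(p - mu)^2 / (2 * s2^2)), data = df,
    start = list(c0 = min(sm), A = max(sm) - min(sm), mu = pc[imax],
                 s2 = 25),
    control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (is.finite(cf[["mu"]]) && cf[["A"]] > 0 &&
        cf[["mu"]] > min(pc) && cf[["mu"]] < max(pc)) {
      map <- cf[["mu"]]
      amax <- max(amax, cf[["c0"]] + cf[["A"]])
    }
  }
  if (is.na(map)) {
    near <- which(sm >= 0.3 * sm[imax])
    if (length(near) >= 5L) {
      b <- stats::lm.wfit(cbind(1, pc[near], pc[near]^2), log(sm[near]),
                          sm[near]^2)$coefficients
      v <- -b[2] / (2 * b[3])
      if (is.finite(v) && b[3] < 0 && v >= min(pc[near]) &&
          v <= max(pc[near])) map <- unname(v)
    }
  }
  if (is.na(map)) map <- pc[imax]

  cross <- function(side, ratio) {
    lev <- ratio * amax
    if (side == "high") {
      idx <- which(pc > map)
      idx <- idx[order(pc[idx], decreasing = TRUE)]   # from highest pressure
    } else {
      idx <- which(pc < map)
      idx <- idx[order(pc[idx])]                      # from lowest pressure
    }
    if (length(idx) < 2L)
      stop("envelope does not extend beyond MAP on the ", side,
           "-pressure side", call. = FALSE)
    for (j in seq_len(length(idx) - 1L)) {
      a1 <- sm[idx[j]]; a2 <- sm[idx[j + 1L]]
      if ((a1 - lev) * (a2 - lev) <= 0) {
        p1 <- pc[idx[j]]; p2 <- pc[idx[j + 1L]]
        if (a2 == a1) return(p1)
        return(p1 + (lev - a1) / (a2 - a1) * (p2 - p1))
      }
    }
    stop("envelope never falls to the ", side, "-side characteristic ratio",
         call. = FALSE)
  }
  sbp <- cross("high", systolic_ratio)
  dbp <- cross("low", diastolic_ratio)
  if (!(dbp < map && map < sbp))
    stop("inconsistent envelope estimates (need dbp < map < sbp)",
         call. = FALSE)
  structure(list(sbp = sbp, map = map, dbp = dbp, method = "envelope_ratio",
                 systolic_ratio = systolic_ratio,
                 diastolic_ratio = diastolic_ratio,
                 envelope = data.frame(cuff = pc, amplitude = a,
                                       smoothed = sm)),
            class = "brachial_estimate")
}

#' @export
print.brachial_estimate <- function(x, ...) {
  cat(sprintf("<brachial_estimate> SBP %.1f  MAP %.1f  DBP %.1f mmHg (ratios %.2f/%.2f)\n",
              x$sbp, x$map, x$dbp, x$systolic_ratio, x$diastolic_ratio))
  invisible(x)
}

#' Residuum artifact score
#'
#' The residuum is the part of the raw signal explained neither by the
#' fitted deflation ramp nor by the cardiac-band pulsatile component
#' (zero-phase bandpass 0.5-10 Hz). Its RMS is computed per window; windows
#' exceeding the threshold are flagged, and the recording as a whole is
#' flagged when more than `flag_fraction` of windows are, mirroring the
#' invasive arrhythmia rule.
#'
#' @param rec An `oscillometric_recording`.
#' @param window Window length, seconds (default 2).
#' @param threshold RMS flag threshold, mmHg (default 1.5).
#' @param flag_fraction Recording-level flag fraction (default 0.30,
#'   strict).
#' @return List `windows` (data.frame `t_start`, `score`, `flagged`),
#'   `recording_flag`.
#' @export
residuum_score <- function(rec, window = 2, threshold = 1.5,
                           flag_fraction = 0.30) {
  stopifnot(inherits(rec, "oscillometric_recording"))
  fs <- rec$raw$sampling_rate
  recon <- filt_zp(rec$pulsatile, fs, c(0.5, min(10, 0.45 * fs)),
                   type = "pass")
  resid <- rec$pulsatile - recon
  wn <- max(1L, round(window * fs))
  n <- length(resid)
  starts <- seq(1L, n, by = wn)
  score <- vapply(starts, function(s) {
    seg <- resid[s:min(n, s + wn - 1L)]
    sqrt(mean(seg^2))
  }, numeric(1))
  flagged <- score > threshold
  list(windows = data.frame(t_start = rec$time[starts], score = score,
                            flagged = flagged),
       recording_flag = mean(flagged) > flag_fraction)
}

#' Central pressure estimate from the calibrated ensemble pulse
#'
#' Pulses whose cuff pressure lies within `ensemble_band` mmHg of the
#' envelope MAP are resampled to a common length, amplitude-normalized and
#' averaged into an ensemble pulse. The ensemble is then calibrated so that
#' its time-average equals the brachial MAP and its minimum the brachial
#' DBP (the recalibrated MAP and DBP serve as the calibration, an internal
#' preprocessing step). The calibrated pulse is handed to a registered
#' estimator (see [register_estimator()]); the default `"ratio_surrogate"`
#' is a deliberately simple, clearly labelled stand-in for any proprietary
#' transfer function: `cdbp = dbp`, `cmap = map`,
#' `csbp = map + alpha * (max(calibrated pulse) - map)`.
#'
#' @param rec An `oscillometric_recording` after [find_pulses()].
#' @param brachial A `brachial_estimate`.
#' @param estimator Estimator id (default `"ratio_surrogate"`).
#' @param ensemble_band Half-width of the cuff-pressure selection band
#'   around MAP, mmHg (default 15).
#' @param ... Passed to the estimator (e.g. `alpha`).
#' @return A `central_estimate`: `csbp`, `cmap`, `cdbp`, `estimator_id`,
#'   `calibration` (map, dbp used), `ensemble` (calibrated pulse samples).
#' @export
estimate_central <- function(rec, brachial, estimator = "ratio_surrogate",
                             ensemble_band = 15, ...) {
  stopifnot(inherits(rec, "oscillometric_recording"),
            inherits(brachial, "brachial_estimate"))
  if (is.null(rec$pulses)) stop("run find_pulses() first", call. = FALSE)
  pu <- rec$pulses[rec$pulses$detected, , drop = FALSE]
  sel <- which(abs(pu$cuff - brachial$map) <= ensemble_band)
  if (length(sel) < 2L)
    stop("no pulses within the ensemble band around MAP", call. = FALSE)
  feet <- pu$foot
  all_feet <- sort(unique(c(feet, feet[length(feet)] +
                              round(stats::median(diff(feet))))))
  npts <- 100L
  shapes <- vapply(sel, function(i) {
    f0 <- pu$foot[i]
    nxt <- all_feet[all_feet > f0][1]
    seg <- rec$filtered[f0:min(nxt, length(rec$filtered))]
    seg <- stats::approx(seq_along(seg), seg, n = npts)$y
    (seg - min(seg)) / (max(seg) - min(seg))
  }, numeric(npts))
  ens <- rowMeans(shapes)
  a <- (brachial$map - brachial$dbp) / (trapz_mean(ens) - min(ens))
  b <- brachial$dbp - a * min(ens)
  cal <- a * ens + b
  fn <- get_estimator(estimator)
  est <- fn(cal, brachial, ...)
  if (!(est$cdbp <= est$cmap && est$cmap <= est$csbp))
    stop("estimator returned inconsistent pressures (need cdbp <= cmap <= csbp)",
         call. = FALSE)
  structure(list(csbp = est$csbp, cmap = est$cmap, cdbp = est$cdbp,
                 estimator_id = estimator,
                 calibration = c(map = brachial$map, dbp = brachial$dbp),
                 ensemble = cal),
            class = "central_estimate")
}

#' @export
print.central_estimate <- function(x, ...) {
  cat(sprintf("<central_estimate> [%s] cSBP %.1f  cMAP %.1f  cDBP %.1f mmHg\n",
              x$estimator_id, x$csbp, x$cmap, x$cdbp))
  invisible(x)
}

#' Full oscillometric analysis of one cuff recording
#'
#' Convenience wrapper chaining [separate_pulsatile()], [find_pulses()],
#' [envelope_bp()], [residuum_score()] and [estimate_central()].
#'
#' @param raw Cuff `pressure_waveform`.
#' @param estimator Estimator id.
#' @param ... Passed to [envelope_bp()].
#' @return List `recording`, `brachial`, `central`, `residuum`.
#' @export
analyze_oscillometric <- function(raw, estimator = "ratio_surrogate", ...) {
  rec <- separate_pulsatile(raw)
  rec <- find_pulses(rec)
  brachial <- envelope_bp(rec, ...)
  central <- estimate_central(rec, brachial, estimator = estimator)
  list(recording = rec, brachial = brachial, central = central,
       residuum = residuum_score(rec))
}
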