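#' @title Per-beat analysis of invasive aortic pressure recordings
#' @description Beat segmentation at pulse foot points, per-beat systolic /
#'   diastolic / mean values, automated outlier clearing, recording summary
#'   statistics and the hemodynamic-stability and arrhythmia inclusion rules
#'   applied to every recording before it may enter a validation analysis.
#' @name invasive-analysis
NULL

# Shared foot-point detector. Feet are the local minima preceding each
# maximal-upstroke point; upstrokes are located where the derivative of the
# lowpass-filtered signal crosses `slope_frac` of its peak, with a
# refractory period between beats. The lowpass (zero-phase, default 20 Hz)
# keeps the derivative noise well below physiologic upstroke slopes at any
# sampling rate.
detect_feet <- function(x, fs, slope_frac = 0.4, refractory = 0.25,
                        min_range = 5, lp_cutoff = 20) {
  n <- length(x)
  if (diff(range(x)) < min_range)
    stop("no beats: signal is flat (range < ", min_range, " mmHg)",
         call. = FALSE)
  xs <- filt_zp(x, fs, lp_cutoff)
  d <- diff(xs) * fs
  thr <- slope_frac * max(d)
  if (thr <= 0) stop("no beats: no positive upstroke found", call. = FALSE)
  up <- which(d[-1] >= thr & d[-length(d)] < thr) + 1L
  if (length(up) < 2L) stop("no beats: fewer than 2 upstrokes", call. = FALSE)

  # refractory applies cumulatively from the last kept upstroke
  ref_n <- round(refractory * fs)
  last <- up[1]; kept <- up[1]
  for (u in up[-1]) {
    if (u - last >= ref_n) { kept <- c(kept, u); last <- u }
  }
  up <- kept

  # foot = end of the diastolic valley: the last sample (before the
  # upstroke crossing) still within a small tolerance of the window
  # minimum. Taking the plain argmin instead can land anywhere on the flat
  # noisy valley, far from the upstroke.
  back <- round(0.4 * fs)
  feet <- integer(length(up))
  prev <- 1L
  for (j in seq_along(up)) {
    lo <- max(prev, up[j] - back, 1L)
    seg <- xs[lo:up[j]]
    near_min <- which(seg <= min(seg) + 0.2)
    feet[j] <- lo + near_min[length(near_min)] - 1L
    prev <- up[j]
  }
  feet <- unique(feet)
  # reject false feet (e.g. at the dicrotic notch): a true foot is followed
  # by a full systolic upstroke, a false one only by the small notch
  # recovery. Rise is measured over a forward window of a third of the
  # median cycle.
  if (length(feet) >= 3L) {
    med_int <- stats::median(diff(feet))
    fwd <- max(3L, round(0.35 * med_int))
    rise <- vapply(feet, function(f0)
      max(xs[f0:min(n, f0 + fwd)]) - xs[f0], numeric(1))
    ok <- rise >= 0.35 * stats::median(rise)
    if (any(ok)) feet <- feet[ok]
  }
  # physiologic filtering: intervals implying > 180 beats/min, or shorter
  # than 0.55 x the median cycle (a foot falsely detected at the dicrotic
  # notch sits high on the diastolic decay: drop the higher-pressure foot)
  repeat {
    if (length(feet) < 3L) break
    ints <- diff(feet)
    short <- which(ints < max(60 / 180 * fs, 0.55 * stats::median(ints)))
    if (length(short) == 0L) break
    j <- short[1]
    drop <- if (xs[feet[j]] > xs[feet[j + 1L]]) j else j + 1L
    feet <- feet[-drop]
  }
  if (length(feet) < 2L) stop("no beats: fewer than 2 feet", call. = FALSE)
  feet
}

#' Detect beats in an invasive pressure waveform
#'
#' Segments an invasive aortic recording into whole beats at pulse foot
#' points (the diastolic minimum preceding each systolic upstroke). Partial
#' beats before the first and after the last foot are dropped; beats are
#' half-open sample-index intervals `[start, end)`.
#'
#' @param waveform A `pressure_waveform` with channel `"invasive"`.
#' @param slope_frac Upstroke detection threshold as a fraction of the
#'   recording's peak positive (filtered) slope. Default 0.25, low enough
#'   that the weaker upstrokes of low-pulse-pressure extrasystoles are
#'   still detected; false triggers at the dicrotic notch are rejected by
#'   the subsequent upstroke-rise check.
#' @param refractory Minimum time between upstrokes, seconds. Default 0.25.
#' @return A data.frame with columns `start`, `end` (half-open indices) and
#'   `t_foot` (seconds). An attribute `"rate_warning"` is set if the implied
#'   dominant beat rate falls outside 30-180/min.
#' @export
detect_beats <- function(waveform, slope_frac = 0.25, refractory = 0.25) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  if (waveform$channel != "invasive")
    stop("detect_beats expects an invasive channel", call. = FALSE)
  if (waveform_duration(waveform) < 2)
    stop("recording shorter than 2 s", call. = FALSE)
  feet <- detect_feet(waveform$samples, waveform$sampling_rate,
                      slope_frac = slope_frac, refractory = refractory)
  beats <- data.frame(start = feet[-length(feet)], end = feet[-1])
  beats$t_foot <- waveform$t0 + (beats$start - 1L) / waveform$sampling_rate
  rate <- 60 * waveform$sampling_rate / stats::median(diff(feet))
  attr(beats, "rate_warning") <- rate < 30 || rate > 180
  beats
}

#' Per-beat pressure values
#'
#' For each beat: systolic pressure is the peak sample, diastolic the lowest
#' sample (both over the half-open beat interval), and MAP the trapezoidal
#' time-average of the closed beat (area under the curve divided by beat
#' duration).
#'
#' @param waveform A `pressure_waveform`.
#' @param beats Data.frame with `start`, `end` columns as from
#'   [detect_beats()].
#' @return `beats` with added columns `sbp`, `dbp`, `map`, `kept` (all TRUE)
#'   and `exclusion_reason` (`"none"`).
#' @export
beat_values <- function(waveform, beats) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  n <- length(waveform$samples)
  if (nrow(beats) < 1L) stop("no beats supplied", call. = FALSE)
  if (any(beats$start < 1L) || any(beats$end > n) ||
      any(beats$end <= beats$start))
    stop("beat bounds outside waveform", call. = FALSE)
  x <- waveform$samples
  beats$sbp <- vapply(seq_len(nrow(beats)), function(i)
    max(x[beats$start[i]:(beats$end[i] - 1L)]), numeric(1))
  beats$dbp <- vapply(seq_len(nrow(beats)), function(i)
    min(x[beats$start[i]:(beats$end[i] - 1L)]), numeric(1))
  beats$map <- vapply(seq_len(nrow(beats)), function(i)
    trapz_mean(x[beats$start[i]:beats$end[i]]), numeric(1))
  beats$duration_s <- (beats$end - beats$start) / waveform$sampling_rate
  beats$kept <- TRUE
  beats$exclusion_reason <- "none"
  beats
}

#' Clear outlier beats
#'
#' Automated version of visual artifact clearing: a beat is excluded when
#' its systolic or diastolic value deviates from the per-recording median
#' by more than `k` robust-SD units, where robust SD is 1.4826 times the
#' median absolute deviation, floored at 1 mmHg (sub-millimetre
#' beat-to-beat differences are never artifacts, and the floor keeps the
#' rule defined for near-identical beat trains). In addition, beats whose
#' cycle length falls outside `short_fraction` to `long_fraction` of the
#' median cycle are excluded: a cycle shortened by more than a quarter is
#' the signature of a premature (extrasystolic) beat, and an overlong
#' "beat" is a segmentation artifact spanning more than one cardiac cycle.
#' The ratio form stays reliable even when heavy ectopy would inflate a
#' deviation-based scale estimate. The rule is computed from all detected
#' beats, so re-running it never changes the result.
#'
#' @param beats Data.frame from [beat_values()].
#' @param k Deviation threshold in robust-SD units. Default 3.
#' @param short_fraction,long_fraction Acceptable cycle-length band as
#'   fractions of the median cycle (defaults 0.75 and 1.5).
#' @return `beats` with updated `kept` / `exclusion_reason`.
#' @export
clear_outlier_beats <- function(beats, k = 3, short_fraction = 0.75,
                                long_fraction = 1.5) {
  if (nrow(beats) < 3L)
    stop("need at least 3 beats for outlier clearing", call. = FALSE)
  rsd <- function(v) max(stats::mad(v), 1.0)
  dev <- function(v) abs(v - stats::median(v))
  out <- dev(beats$sbp) > k * rsd(beats$sbp) |
         dev(beats$dbp) > k * rsd(beats$dbp)
  if (!is.null(beats$duration_s)) {
    med_d <- stats::median(beats$duration_s)
    out <- out | beats$duration_s < short_fraction * med_d |
           beats$duration_s > long_fraction * med_d
  }
  beats$kept <- !out
  beats$exclusion_reason <- ifelse(out, "outlier", "none")
  if (all(out)) stop("recording unusable: all beats excluded", call. = FALSE)
  beats
}

#' Summarize a beat series
#'
#' Means and sample standard deviations (n-1 denominator) of SBP, DBP and MAP
#' over kept beats, plus exclusion accounting over all detected beats. With a
#' single kept beat the SDs are 0 by convention.
#'
#' @param beats Data.frame with `sbp`, `dbp`, `map`, `kept`.
#' @return A `recording_summary` list: `mean_sbp`, `mean_dbp`, `mean_map`,
#'   `sd_sbp`, `sd_dbp`, `sd_map`, `n_beats_total`, `n_beats_excluded`,
#'   `excluded_fraction`.
#' @export
summarize_recording <- function(beats) {
  kept <- beats[beats$kept, , drop = FALSE]
  if (nrow(kept) < 1L) stop("zero kept beats", call. = FALSE)
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  s <- list(
    mean_sbp = mean(kept$sbp), mean_dbp = mean(kept$dbp),
    mean_map = mean(kept$map),
    sd_sbp = sd0(kept$sbp), sd_dbp = sd0(kept$dbp), sd_map = sd0(kept$map),
    n_beats_total = nrow(beats),
    n_beats_excluded = sum(!beats$kept)
  )
  s$excluded_fraction <- s$n_beats_excluded / s$n_beats_total
  structure(s, class = "recording_summary")
}

#' @export
print.recording_summary <- function(x, ...) {
  cat(sprintf("<recording_summary> %d beats (%d excluded, %.1f%%)\n",
              x$n_beats_total, x$n_beats_excluded,
              100 * x$excluded_fraction))
  cat(sprintf("  SBP %.1f (SD %.2f)  MAP %.1f (SD %.2f)  DBP %.1f (SD %.2f) mmHg\n",
              x$mean_sbp, x$sd_sbp, x$mean_map, x$sd_map,
              x$mean_dbp, x$sd_dbp))
  invisible(x)
}

#' Apply recording-level inclusion rules
#'
#' A recording is withdrawn for severe arrhythmia when more than
#' `arrhythmia_threshold` (strictly) of its pulse waves had to be cleared,
#' and for hemodynamic instability when the beat-to-beat SD strictly exceeds
#' the per-component thresholds (defaults 10 mmHg systolic, 6 mmHg diastolic,
#' 6 mmHg MAP). The arrhythmia rule is checked first. Stability sub-reasons
#' are attributed in the order SBP, MAP, DBP.
#'
#' @param summary A `recording_summary`.
#' @param sd_limits Named numeric `c(sbp = 10, map = 6, dbp = 6)`, mmHg.
#' @param arrhythmia_threshold Maximum tolerated cleared-beat fraction
#'   (strict). Default 0.30.
#' @return List with `verdict` (`"include"`, `"exclude_arrhythmia"`,
#'   `"exclude_stability"`) and `detail` (for stability: which SD triggered,
#'   `"sd_sbp"` / `"sd_map"` / `"sd_dbp"`).
#' @export
apply_exclusion_rules <- function(summary,
                                  sd_limits = c(sbp = 10, map = 6, dbp = 6),
                                  arrhythmia_threshold = 0.30) {
  stopifnot(inherits(summary, "recording_summary"))
  if (summary$excluded_fraction > arrhythmia_threshold)
    return(list(verdict = "exclude_arrhythmia",
                detail = sprintf("%.1f%% of beats cleared",
                                 100 * summary$excluded_fraction)))
  if (summary$sd_sbp > sd_limits[["sbp"]])
    return(list(verdict = "exclude_stability", detail = "sd_sbp"))
  if (summary$sd_map > sd_limits[["map"]])
    return(list(verdict = "exclude_stability", detail = "sd_map"))
  if (summary$sd_dbp > sd_limits[["dbp"]])
    return(list(verdict = "exclude_stability", detail = "sd_dbp"))
  list(verdict = "include", detail = "")
}

#' Full invasive analysis of one recording
#'
#' Convenience wrapper: [detect_beats()], [beat_values()],
#' [clear_outlier_beats()], [summarize_recording()],
#' [apply_exclusion_rules()].
#'
#' @param waveform Invasive `pressure_waveform`.
#' @param k Outlier-clearing threshold (robust-SD units).
#' @param sd_limits,arrhythmia_threshold Passed to
#'   [apply_exclusion_rules()].
#' @return List `beats`, `summary`, `verdict`, `detail`.
#' @export
analyze_invasive <- function(waveform, k = 3,
                             sd_limits = c(sbp = 10, map = 6, dbp = 6),
                             arrhythmia_threshold = 0.30) {
  beats <- detect_beats(waveform)
  beats <- beat_values(waveform, beats)
  beats <- clear_outlier_beats(beats, k = k)
  s <- summarize_recording(beats)
  v <- apply_exclusion_rules(s, sd_limits = sd_limits,
                             arrhythmia_threshold = arrhythmia_threshold)
  list(beats = beats, summary = s, verdict = v$verdict, detail = v$detail)
}
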