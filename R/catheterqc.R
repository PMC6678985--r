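#' @title Catheter frequency-response quality control
#' @description A fluid-filled catheter-transducer system behaves as an
#'   underdamped second-order system. Its natural frequency and damping
#'   coefficient are estimated from the ring-down oscillations of a fast
#'   flush test: the frequency from the time between the 2nd and 3rd
#'   oscillation (one full cycle), the damping from the amplitude ratio of
#'   those two oscillations via the logarithmic decrement.
#' @name catheter-qc
NULL

#' Detect flush ring-down oscillations
#'
#' Locates the flush release (the steepest pressure drop), takes the settled
#' baseline as the mean of the final 20% of the signal, and returns the
#' successive oscillation extrema after release with sub-sample quadratic
#' refinement of both time and amplitude. Amplitudes are absolute deviations
#' from the settled baseline.
#'
#' @param waveform A `pressure_waveform` with channel `"flush"`.
#' @param min_amplitude Smallest extremum amplitude considered real, mmHg.
#'   Default 0.15.
#' @return Data.frame with columns `time` (s), `amplitude` (mmHg, >= 0) and
#'   `type` (`"min"` / `"max"`), in time order.
#' @export
detect_oscillations <- function(waveform, min_amplitude = 0.15) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  if (waveform$channel != "flush")
    stop("detect_oscillations expects a flush channel", call. = FALSE)
  x <- waveform$samples
  fs <- waveform$sampling_rate
  n <- length(x)
  baseline <- mean(x[max(1L, floor(0.8 * n)):n])
  release <- which.min(diff(x))
  y <- x - baseline

  post <- y[(release + 1L):n]
  # rough ring frequency from the dominant spectral peak of the ring-down
  m0 <- length(post)
  sp <- Mod(stats::fft(post - mean(post)))[2:max(3L, floor(m0 / 2))]
  freqs <- seq_along(sp) * fs / m0
  f_rough <- min(max(freqs[which.max(sp)], 2), fs / 4)
  # zero-phase lowpass well above the ring frequency: kills noise without
  # biasing extremum times, and attenuates both compared amplitudes equally
  ys <- filt_zp(y, fs, 3 * f_rough)

  d <- diff(ys)
  ext <- which(d[-1] * d[-length(d)] < 0) + 1L
  ext <- ext[ext > release + 2L & ext < n - 2L]
  # enforce half-cycle spacing, then truncate at the first extremum that has
  # decayed into the noise floor -- everything later is noise
  if (length(ext) > 1L) {
    min_gap <- round(0.3 * fs / f_rough)
    keep <- ext[1]
    for (e in ext[-1]) if (e - keep[length(keep)] >= min_gap) keep <- c(keep, e)
    ext <- keep
  }
  below <- which(abs(ys[ext]) < min_amplitude)
  if (length(below) > 0) ext <- ext[seq_len(below[1] - 1L)]
  if (length(ext) < 3L)
    stop("no oscillations: fewer than 3 extrema after release", call. = FALSE)

  # quadratic vertex refinement over ~1/8 period around each extremum
  m <- max(2L, round(fs / (8 * f_rough)))
  refine <- function(i) {
    lo <- max(release + 1L, i - m); hi <- min(n, i + m)
    idx <- lo:hi
    fit <- stats::lm.fit(cbind(1, idx, idx^2), ys[idx])
    b <- fit$coefficients
    if (!is.finite(b[3]) || b[3] == 0) return(c(i, ys[i]))
    v <- -b[2] / (2 * b[3])
    if (v < lo || v > hi) v <- i
    c(v, b[1] + b[2] * v + b[3] * v^2)
  }
  ref <- t(vapply(ext, refine, numeric(2)))
  out <- data.frame(
    time = waveform$t0 + (ref[, 1] - 1) / fs,
    amplitude = abs(ref[, 2]),
    type = ifelse(ys[ext] < 0, "min", "max")
  )
  # enforce alternation: within runs of equal type keep the largest
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    if (out$type[i] == out$type[i - 1]) {
      if (out$amplitude[i] > out$amplitude[i - 1]) keep[i - 1] <- FALSE
      else keep[i] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out) < 3L)
    stop("no oscillations: fewer than 3 extrema after release", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Natural frequency from one oscillation cycle
#'
#' The time between the 2nd and 3rd oscillation is one full period, so the
#' frequency is its reciprocal. Note this measures the ringing (damped)
#' frequency; see [analyze_flush_test()] for the optional undamped
#' correction.
#'
#' @param t2,t3 Times (s) of the 2nd and 3rd oscillation (same-sign extrema
#'   one cycle apart).
#' @return Frequency in Hz.
#' @export
natural_frequency <- function(t2, t3) {
  if (!(t3 > t2)) stop("t3 must exceed t2", call. = FALSE)
  1 / (t3 - t2)
}

#' Damping coefficient from consecutive oscillation amplitudes
#'
#' Logarithmic decrement: with `delta = log(A2/A3)` for two same-sign
#' extrema one period apart, the damping ratio of a second-order system is
#' `zeta = delta / sqrt(4*pi^2 + delta^2)`.
#'
#' @param a2,a3 Amplitudes (mmHg, relative to settled baseline) of the 2nd
#'   and 3rd oscillation; requires `a2 > a3 > 0` (a damped system).
#' @return Damping ratio in (0, 1).
#' @export
damping_coefficient <- function(a2, a3) {
  if (!(a3 > 0) || !(a2 > a3))
    stop("need a2 > a3 > 0 (undamped or growing oscillation otherwise)",
         call. = FALSE)
  delta <- log(a2 / a3)
  delta / sqrt(4 * pi^2 + delta^2)
}

#' Check a flush-test result against acceptance ranges
#'
#' Inclusive range check of natural frequency and damping coefficient. The
#' default ranges are those observed across the study's catheter systems
#' (15-29 Hz, 0.14-0.29); both are configurable to encode guideline limits.
#'
#' @param result A `flush_test_result` from [analyze_flush_test()].
#' @param fn_range,zeta_range Numeric length-2 acceptance ranges.
#' @return List `qc_pass` (logical) and `report` (one text line).
#' @export
qc_check <- function(result, fn_range = c(15, 29),
                     zeta_range = c(0.14, 0.29)) {
  stopifnot(inherits(result, "flush_test_result"))
  ok_f <- result$natural_frequency >= fn_range[1] &&
    result$natural_frequency <= fn_range[2]
  ok_z <- result$damping_coefficient >= zeta_range[1] &&
    result$damping_coefficient <= zeta_range[2]
  list(qc_pass = ok_f && ok_z,
       report = sprintf(
         "fn = %.1f Hz [%g-%g: %s], zeta = %.2f [%g-%g: %s]",
         result$natural_frequency, fn_range[1], fn_range[2],
         if (ok_f) "ok" else "FAIL",
         result$damping_coefficient, zeta_range[1], zeta_range[2],
         if (ok_z) "ok" else "FAIL"))
}

#' Characterize a catheter system from a flush test
#'
#' Runs [detect_oscillations()], takes the 2nd and 3rd same-sign extrema
#' after release (one cycle apart), and computes natural frequency and
#' damping coefficient from them, plus the QC verdict.
#'
#' The one-cycle timing rule measures the damped (ringing) frequency
#' `fd = fn * sqrt(1 - zeta^2)`. By default the measured value is reported
#' as-is, matching routine catheter-lab practice; with
#' `undamped_correction = TRUE` the estimate is corrected to the undamped
#' natural frequency `fn = fd / sqrt(1 - zeta^2)`.
#'
#' @param waveform Flush `pressure_waveform`.
#' @param fn_range,zeta_range Acceptance ranges for [qc_check()].
#' @param undamped_correction Report the undamped natural frequency instead
#'   of the raw one-cycle frequency. Default FALSE.
#' @return A `flush_test_result`: `natural_frequency` (Hz),
#'   `damping_coefficient`, `oscillation_times`, `oscillation_amplitudes`,
#'   `qc_pass`, `qc_report`.
#' @export
analyze_flush_test <- function(waveform, fn_range = c(15, 29),
                               zeta_range = c(0.14, 0.29),
                               undamped_correction = FALSE) {
  ext <- detect_oscillations(waveform)
  same <- ext[ext$type == ext$type[1], , drop = FALSE]
  if (nrow(same) < 3L)
    stop("no oscillations: fewer than 3 same-sign extrema", call. = FALSE)
  fn <- natural_frequency(same$time[2], same$time[3])
  zeta <- damping_coefficient(same$amplitude[2], same$amplitude[3])
  if (undamped_correction) fn <- fn / sqrt(1 - zeta^2)
  res <- structure(
    list(natural_frequency = fn, damping_coefficient = zeta,
         oscillation_times = same$time, oscillation_amplitudes = same$amplitude,
         extrema = ext),
    class = "flush_test_result")
  qc <- qc_check(res, fn_range = fn_range, zeta_range = zeta_range)
  res$qc_pass <- qc$qc_pass
  res$qc_report <- qc$report
  res
}

#' @export
print.flush_test_result <- function(x, ...) {
  cat("<flush_test_result>", x$qc_report,
      if (x$qc_pass) "- PASS\n" else "- FAIL\n")
  invisible(x)
}
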