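#' Pressure waveform container
#'
#' A uniformly sampled pressure signal in mmHg, the basic currency of the
#' package. Invasive aortic recordings, cuff-deflation recordings and catheter
#' flush tests are all `pressure_waveform` objects distinguished by their
#' `channel`.
#'
#' @param samples Numeric vector of pressure samples in mmHg. Must be finite
#'   and of length >= 2.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel One of `"invasive"`, `"cuff"`, `"flush"`.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param ground_truth Optional list of generator ground truth (kept as an
#'   attribute; synthetic signals carry their construction parameters here).
#'
#' @return An object of class `pressure_waveform`: a list with elements
#'   `samples`, `sampling_rate`, `channel`, `t0`.
#' @export
pressure_waveform <- function(samples, sampling_rate,
                              channel = c("invasive", "cuff", "flush"),
                              t0 = 0, ground_truth = NULL) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a pressure waveform needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("pressure samples must be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  w <- structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         channel = channel, t0 = as.numeric(t0)),
    class = "pressure_waveform"
  )
  if (!is.null(ground_truth)) attr(w, "ground_truth") <- ground_truth
  w
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("<pressure_waveform> channel=%s, %d samples @ %g Hz (%.1f s), range %.1f-%.1f mmHg\n",
              x$channel, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              min(x$samples), max(x$samples)))
  invisible(x)
}

# Zero-phase Butterworth lowpass/bandpass with mirror padding at both ends
# (signal::filtfilt alone produces large startup transients on signals with
# a nonzero initial level).
filt_zp <- function(x, fs, cutoff, type = "low", order = 2) {
  n <- length(x)
  w <- pmin(cutoff / (fs / 2), 0.9)
  bf <- signal::butter(order, w, type = type)
  np <- min(n - 1L, max(16L, round(3 * fs / min(cutoff))))
  xp <- c(rev(x[2:(np + 1L)]), x, rev(x[(n - np):(n - 1L)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1L):(np + n)]
}

#' Time axis of a waveform
#'
#' @param w A `pressure_waveform`.
#' @return Numeric vector of sample times in seconds.
#' @export
waveform_time <- function(w) {
  stopifnot(inherits(w, "pressure_waveform"))
  w$t0 + (seq_along(w$samples) - 1L) / w$sampling_rate
}

#' Duration of a waveform in seconds
#' @param w A `pressure_waveform`.
#' @export
waveform_duration <- function(w) {
  stopifnot(inherits(w, "pressure_waveform"))
  (length(w$samples) - 1L) / w$sampling_rate
}

#' Resample a waveform to a new rate
#'
#' Linear interpolation onto a uniform grid at `new_rate`. Used for
#' sampling-rate robustness checks across the recording systems' native rates
#' (240, 500, 2000 Hz).
#'
#' @param w A `pressure_waveform`.
#' @param new_rate Target sampling rate in Hz.
#' @return A `pressure_waveform` at `new_rate` covering the same time span.
#' @export
resample_waveform <- function(w, new_rate) {
  stopifnot(inherits(w, "pressure_waveform"), new_rate > 0)
  t_old <- waveform_time(w)
  n_new <- floor(waveform_duration(w) * new_rate) + 1L
  t_new <- w$t0 + (seq_len(n_new) - 1L) / new_rate
  y <- stats::approx(t_old, w$samples, xout = t_new, rule = 2)$y
  pressure_waveform(y, new_rate, channel = w$channel, t0 = w$t0,
                    ground_truth = attr(w, "ground_truth"))
}
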