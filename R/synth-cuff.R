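#' Synthesize an oscillometric cuff-deflation recording
#'
#' A linear cuff deflation with superimposed cardiac pulses whose amplitudes
#' follow a Gaussian envelope in (cuff pressure - MAP), so the envelope
#' maximum sits at the true mean arterial pressure -- the standard
#' idealization of the oscillometric principle. Pulse shapes reuse the
#' aortic beat morphology, zero-meaned per cycle.
#'
#' @param true_bp Numeric length-3: true (sbp, map, dbp) in mmHg.
#' @param heart_rate Beats/min.
#' @param deflation_rate Deflation speed, mmHg/s (default 4, a regulated
#'   linear valve).
#' @param sampling_rate Hz; must be at least `8 * heart_rate / 60` to
#'   resolve pulses. Default 100.
#' @param start_pressure Deflation start, mmHg; must exceed systolic by more
#'   than 30 mmHg. Default `sbp + 40`.
#' @param end_pressure Deflation end, mmHg. Default 30, low enough that the
#'   envelope falls below the diastolic characteristic ratio even for
#'   low-MAP patients.
#' @param envelope_width Gaussian envelope SD in mmHg (default 25).
#' @param max_amplitude Peak pulse amplitude at MAP, mmHg (default 3).
#' @param hr_cv Beat-period coefficient of variation (default 0.02).
#' @param noise_sd Additive white noise SD, mmHg (default 0.5).
#' @param rng_seed Integer seed.
#' @return A `pressure_waveform` (channel `"cuff"`) whose ground truth holds
#'   `true_bp`, `deflation_rate`, and per-pulse `feet` (sample indices),
#'   `cuff_at_foot` and `amplitude`.
#' @export
synth_cuff_recording <- function(true_bp, heart_rate, deflation_rate = 4,
                                 sampling_rate = 100,
                                 start_pressure = true_bp[1] + 40,
                                 end_pressure = 30,
                                 envelope_width = 25, max_amplitude = 3,
                                 hr_cv = 0.02, noise_sd = 0.5,
                                 rng_seed = 1L) {
  sbp <- true_bp[1]; map <- true_bp[2]; dbp <- true_bp[3]
  if (!(dbp < map && map < sbp))
    stop("true_bp must satisfy dbp < map < sbp", call. = FALSE)
  if (start_pressure <= sbp + 30)
    stop("deflation must start more than 30 mmHg above systolic",
         call. = FALSE)
  if (deflation_rate <= 0) stop("deflation_rate must be positive",
                                call. = FALSE)
  if (sampling_rate < 8 * heart_rate / 60)
    stop("sampling_rate too low to resolve pulses (need >= 8 x heart rate)",
         call. = FALSE)

  set.seed(rng_seed)
  dur <- (start_pressure - end_pressure) / deflation_rate
  n <- round(dur * sampling_rate) + 1L
  tt <- (0:(n - 1L)) / sampling_rate
  ramp <- start_pressure - deflation_rate * tt

  period <- 60 / heart_rate
  x <- ramp
  foot_idx <- integer(0); cuff_at_foot <- numeric(0); amps <- numeric(0)
  t_foot <- stats::runif(1, 0, period)
  # one fixed pulse shape for the whole recording (decay solved once)
  n_shape <- max(10L, round(period * sampling_rate))
  k <- solve_beat_decay(0.4, n_shape, clamp = TRUE)
  while (t_foot + period < dur) {
    Ti <- period * (1 + hr_cv * stats::rnorm(1))
    i0 <- round(t_foot * sampling_rate) + 1L
    i1 <- min(n, i0 + round(Ti * sampling_rate) - 1L)
    if (i1 - i0 < 4L) break
    u <- (0:(i1 - i0)) / (i1 - i0 + 1L)
    w <- beat_shape(u, k)
    w <- w - trapz_mean(c(w, 0))            # zero-mean over the closed cycle
    pc <- ramp[i0]
    A <- max_amplitude * exp(-(pc - map)^2 / (2 * envelope_width^2))
    scale <- A / (max(w) - min(w))
    x[i0:i1] <- x[i0:i1] + scale * w
    foot_idx <- c(foot_idx, i0)
    cuff_at_foot <- c(cuff_at_foot, pc)
    amps <- c(amps, A)
    t_foot <- t_foot + Ti
  }
  if (noise_sd > 0) x <- x + noise_sd * stats::rnorm(n)
  pressure_waveform(x, sampling_rate, channel = "cuff",
                    ground_truth = list(
                      true_bp = c(sbp = sbp, map = map, dbp = dbp),
                      deflation_rate = deflation_rate,
                      start_pressure = start_pressure,
                      feet = foot_idx, cuff_at_foot = cuff_at_foot,
                      amplitude = amps,
                      envelope_width = envelope_width,
                      max_amplitude = max_amplitude))
}
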