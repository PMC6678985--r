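#' Flush-test specification
#'
#' Parameters of a synthetic fast-flush test of a fluid-filled
#' catheter-transducer system, modelled as an underdamped second-order
#' system: after release the pressure rings down to baseline as
#' `baseline + A * exp(-zeta * wn * t) * cos(wd * t)` with `wn = 2*pi*fn`
#' and `wd = wn * sqrt(1 - zeta^2)`.
#'
#' @param natural_frequency Undamped natural frequency `fn`, Hz.
#' @param damping_coefficient Damping ratio `zeta`, in (0, 1).
#' @param baseline_pressure Settled baseline pressure, mmHg. Default 100.
#' @param flush_amplitude Flush plateau pressure, mmHg (>= 180 for a proper
#'   rectangular flush pulse). Default 200.
#' @param sampling_rate Sampling rate, Hz; must exceed 10 times the natural
#'   frequency. Default 1000.
#' @return A `flush_spec` list.
#' @export
flush_spec <- function(natural_frequency, damping_coefficient,
                       baseline_pressure = 100, flush_amplitude = 200,
                       sampling_rate = 1000) {
  if (damping_coefficient <= 0 || damping_coefficient >= 1)
    stop("damping_coefficient must lie in (0, 1): no oscillation otherwise",
         call. = FALSE)
  if (natural_frequency <= 0)
    stop("natural_frequency must be positive", call. = FALSE)
  if (flush_amplitude < 180)
    stop("flush_amplitude must be >= 180 mmHg", call. = FALSE)
  if (sampling_rate <= 10 * natural_frequency)
    stop("sampling_rate must exceed 10 x natural_frequency", call. = FALSE)
  structure(list(natural_frequency = natural_frequency,
                 damping_coefficient = damping_coefficient,
                 baseline_pressure = baseline_pressure,
                 flush_amplitude = flush_amplitude,
                 sampling_rate = sampling_rate),
            class = "flush_spec")
}

#' Synthesize a catheter flush-test recording
#'
#' A plateau at the flush pressure followed by a sudden release and a damped
#' ring-down about the baseline. Ground-truth natural frequency and damping
#' are stored with the waveform. Flush traces are high signal-to-noise
#' transducer recordings, so the default added noise is small (0.1 mmHg SD);
#' it is configurable.
#'
#' @param spec A [flush_spec()].
#' @param duration Post-release duration, seconds; must cover at least 4
#'   oscillation cycles. Default 1.
#' @param plateau Pre-release plateau duration, seconds. Default 0.3.
#' @param noise_sd Additive white noise SD, mmHg. Default 0.1.
#' @param rng_seed Integer seed for the noise.
#' @return A `pressure_waveform` (channel `"flush"`) with ground truth
#'   `natural_frequency`, `damping_coefficient`, `release_time`.
#' @export
synth_flush_test <- function(spec, duration = 1, plateau = 0.3,
                             noise_sd = 0.1, rng_seed = 1L) {
  stopifnot(inherits(spec, "flush_spec"))
  fn <- spec$natural_frequency
  zeta <- spec$damping_coefficient
  fs <- spec$sampling_rate
  wd <- 2 * pi * fn * sqrt(1 - zeta^2)
  if (duration < 4 * (2 * pi / wd))
    stop("duration must cover at least 4 oscillation cycles", call. = FALSE)
  n_pre <- round(plateau * fs)
  n_post <- round(duration * fs)
  tau <- (0:(n_post - 1L)) / fs
  amp <- spec$flush_amplitude - spec$baseline_pressure
  ring <- spec$baseline_pressure +
    amp * exp(-zeta * 2 * pi * fn * tau) * cos(wd * tau)
  x <- c(rep(spec$flush_amplitude, n_pre), ring)
  set.seed(rng_seed)
  if (noise_sd > 0) x <- x + noise_sd * stats::rnorm(length(x))
  pressure_waveform(x, fs, channel = "flush",
                    ground_truth = list(natural_frequency = fn,
                                        damping_coefficient = zeta,
                                        release_time = n_pre / fs,
                                        baseline = spec$baseline_pressure))
}
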