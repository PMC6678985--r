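# shared fixtures: small, fast synthetic signals built in code

# clean beat train: no jitter, no noise -- per-beat values equal the targets
clean_aortic <- function(sbp = 120, dbp = 80, map = 100, hr = 60,
                         duration = 20, fs = 500, seed = 1) {
  synth_aortic_waveform(
    beat_shape_params(sbp, dbp, map, hr, rng_seed = seed),
    duration = duration, sampling_rate = fs,
    beat_sd = c(sbp = 0, map = 0, dbp = 0), hr_cv = 0, noise_sd = 0)
}

# a square beat: first half high, second half low
square_beat_waveform <- function(hi = 120, lo = 80, fs = 100, n_half = 50) {
  pressure_waveform(c(rep(hi, n_half), rep(lo, n_half), hi),
                    fs, channel = "invasive")
}

# tiny cohort for runner tests
tiny_cohort <- function(n = 8, seed = 42, ...) {
  synth_cohort(cohort_spec(n_patients = n, arrhythmia_fraction = 0,
                           stability_fail_fraction = 0,
                           corrupt_fraction = 0, rng_seed = seed, ...))
}
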