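---
title: "Methods: the cbpval validation pipeline"
author: "cbpval authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cbpval validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpval)
```

`cbpval` implements the measurement-and-statistics chain used to validate a
non-invasive central blood pressure (cBP) estimator against an intra-aortic
catheter reference. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic data do and do not
establish.

## Invasive per-beat analysis

A recording is segmented at pulse *foot points* (the diastolic minimum
preceding each systolic upstroke). Per beat, over the half-open interval
between consecutive feet:

- systolic pressure (SBP) = the peak sample,
- diastolic pressure (DBP) = the lowest sample,
- mean arterial pressure (MAP) = the trapezoidal time-average of the closed
  beat — "area under the curve" divided by beat duration. Normalizing the
  integral by duration is the only reading under which
  `DBP <= MAP <= SBP` holds for every beat, so the package treats it as the
  definition.

Recording summaries are means and *sample* standard deviations (n − 1
denominator; a single kept beat reports SD 0 by convention) over kept
beats. Recording-level inclusion applies, in order:

1. **Arrhythmia**: excluded if *strictly more than* 30 % of detected beats
   had to be cleared.
2. **Hemodynamic stability**: excluded if the beat-to-beat SD *strictly
   exceeds* 10 mmHg (SBP), 6 mmHg (MAP) or 6 mmHg (DBP); sub-reasons are
   attributed in the order SBP, MAP, DBP.

Strict inequalities follow the "more than" wording of the underlying
protocol; values exactly at a threshold are included.

### Foot detection

Upstroke candidates are threshold crossings of the derivative of a
zero-phase 20 Hz lowpass-filtered copy of the signal. Three design points
matter, each chosen for robustness across the supported sampling rates
(240–2000 Hz):

- **Filter before differentiating.** A raw first difference has noise
  variance proportional to the sampling rate; at 2000 Hz the derivative of
  the unfiltered signal is noise-dominated and threshold crossings become
  meaningless. The 20 Hz zero-phase Butterworth keeps upstroke timing
  unbiased while pushing derivative noise far below physiologic slopes.
- **Threshold at 25 % of the peak slope.** Extrasystolic beats carry a
  reduced pulse pressure and proportionally weaker upstrokes; a high
  threshold silently drops exactly the beats the arrhythmia rule needs to
  see. The price of a low threshold — occasional false triggers on the
  dicrotic-notch recovery — is paid by an explicit *rise check*: a true
  foot is followed by a near-full systolic rise within a third of the
  median cycle, a notch foot only by the small notch recovery; feet with a
  rise below 35 % of the median rise are discarded.
- **Foot = end of the valley.** The diastolic valley is flat, so the
  argmin of a noisy valley wanders by tens of milliseconds. The foot is
  instead placed at the *last* sample within 0.2 mmHg of the
  backward-window minimum, i.e. where the valley ends and the upstroke
  begins, which is stable and consistent across beats.

Intervals implying more than 180 beats/min, or shorter than 0.55 of the
median cycle, are treated as segmentation faults and the higher-pressure
foot of the offending pair is dropped.

### Beat clearing

The study-style "cleared if they differed greatly from the mean" is
automated as: a beat is excluded when its SBP or DBP deviates from the
per-recording median by more than `k = 3` robust SDs (1.4826 × MAD, floored
at 1 mmHg — sub-millimetre differences are never artifacts, and the floor
keeps the rule defined for near-identical beat trains), **or** when its
cycle length falls outside 0.75–1.5 × the median cycle. The cycle-length
criterion is deliberately a *ratio band*, not another MAD rule: at the
contamination level of a severely arrhythmic recording (≈ 40 % ectopic
beats) a deviation-based scale estimate inflates to the point where the
rule sits exactly at its breakdown — we measured this — while the ratio of
an extrasystole's coupling interval to the median cycle stays far outside
the band. The rule is computed from all detected beats, making re-runs
idempotent.

## Catheter frequency-response QC

A fluid-filled catheter-transducer system is modelled as an underdamped
second-order system. From a fast-flush test the package takes the 2nd and
3rd same-sign ring-down extrema (one full period apart):

- natural frequency `fn = 1/(t3 − t2)`,
- damping ratio from the logarithmic decrement,
  `zeta = delta / sqrt(4*pi^2 + delta^2)` with `delta = log(A2/A3)`,

and checks both against configurable acceptance ranges (defaults 15–29 Hz
and 0.14–0.29, the ranges observed across typical diagnostic catheter
systems; guideline limits can be substituted). Amplitudes are measured
against the settled baseline (mean of the final 20 % of the trace), with
sub-sample quadratic refinement of extremum times and values on a lowpass
copy whose cutoff is three times the dominant ring frequency (found by
FFT).

One subtlety is documented rather than hidden: the one-cycle timing rule
measures the *damped* frequency `fd = fn*sqrt(1 - zeta^2)`. The raw rule is
the default output, matching routine catheter-lab practice; at the upper
end of the damping range the discrepancy exceeds typical recovery
tolerances, so `analyze_flush_test(..., undamped_correction = TRUE)`
applies the second-order correction, and the package's parameter-recovery
properties are stated for the corrected estimate.

## Oscillometric processing

`separate_pulsatile()` finds the monotone deflation segment (with momentary
ripple interruptions under 2 s closed), fits a robust Huber line as the
expected cuff pressure, recentres it so residuals average exactly zero, and
splits the signal into ramp + pulsatile. `residuum_score()` defines the
residuum as raw − ramp − cardiac-band (0.5–10 Hz) pulsatile, scores its RMS
in 2 s windows against a 1.5 mmHg threshold, and raises a recording-level
flag when more than 30 % of windows trip, mirroring the invasive
arrhythmia fraction.

Pulse feet are detected on a 3 Hz lowpass copy of the pulsatile signal;
the foot grid is then *continued periodically* (median beat interval) into
the low-amplitude flanks of the deflation where individual pulses cannot
trigger detection but their residual amplitude still anchors the envelope's
noise floor. Pulse amplitude is max − min per cycle on the same narrow-band
copy; a wider 10 Hz copy retains morphology for the ensemble pulse.

The envelope (amplitude vs cuff pressure at the foot) is smoothed by a
5-pulse moving average, then its maximum is located by fitting a
Gaussian-with-floor model: the floor absorbs the constant upward bias that
noise adds to every max − min amplitude, and the Gaussian centre is the MAP
estimate (with a weighted log-quadratic fit, then the raw maximum, as
fallbacks). This fitting chain is what achieves the package's stated
recovery property — envelope MAP within 2 mmHg at the default noise level —
where a plain argmax with local parabolic refinement does not: the envelope
is sampled only once per heartbeat (about 3.5 mmHg of cuff pressure per
beat at 4 mmHg/s), so peak location must pool information across the whole
usable envelope. Brachial SBP and DBP are the cuff pressures where the
smoothed envelope falls to the systolic (0.55) and diastolic (0.70)
characteristic ratios of the peak, linearly interpolated; the ratios are
configurable and the validation layer does not depend on them.

`estimate_central()` averages the amplitude-normalized pulses whose cuff
pressure lies within ±15 mmHg of envelope MAP, calibrates the ensemble so
its time-average equals brachial MAP and its minimum brachial DBP (the
recalibrated MAP/DBP serve as calibration), and hands the calibrated pulse
to a registered estimator. The shipped `ratio_surrogate`
(`csbp = map + alpha*(pulse_max - map)`, default `alpha = 0.8`;
`cmap = map`, `cdbp = dbp`) is deliberately simple and clearly labelled: it
is a plug-in point, not a reconstruction of any commercial transfer
function. The package's claim is the validation pipeline around the
estimator, not the estimator itself.

## Agreement statistics and grading

Differences are **invasive − estimated** throughout (so a positive mean
means the device underestimates). Per component the package reports mean
difference, sample SD, limits of agreement mean ± 1.96 SD (asserted as an
identity on every result), Pearson r and r² of estimated vs invasive, the
least-squares trend of estimated on invasive, the trend of difference on
pair mean (the sloped line on Bland–Altman plots), and cumulative error
bins |error| < 5/10/15 mmHg with strict inequalities. Percentages are
rounded to one decimal for reporting; the unrounded values are retained.

Grading: ARTERY-2017 passes with |mean| < 5 and SD < 8 mmHg (strict);
AAMI-2013 with ≤ 5 and ≤ 8; AAMI/ESH/ISO-2018 when the normal-model
probability of an error within 10 mmHg,
`100*(Phi((10 - m)/s) - Phi((-10 - m)/s))`, is at least 85 % (the
empirical fraction is reported alongside, since the protocol's exact
estimator is not pinned down); BHS grades use the cumulative thresholds
A: 60/85/95, B: 50/75/90, C: 40/65/85. BHS is graded on *unrounded*
percentages; the grade from rounded percentages is reported as well, with
a flag when the two disagree — near the 85 % boundary the choice genuinely
changes the grade, and publishing both makes the sensitivity visible
instead of silently picking one. Range conformity partitions the invasive
reference values at 100/140/160 mmHg (systolic) and 60/85/100 mmHg
(diastolic), attaches the recommended shares, and reports recruitment as a
whole-percent ratio of the 85-patient goal.

## The synthetic cohort

The generator's defaults encode the validation study's conditions: 191
recruited patients across three site profiles (90 s at 240 Hz, 90 s at
2000 Hz, 20 s at 500 Hz, with recruitment shares 63:50:32); invasive
central pressures with cohort mean (SD) 145.1 (24.0) / 101.5 (14.8) /
72.1 (12.2) mmHg for SBP/MAP/DBP, SBP–DBP correlation 0.6, MAP placed at a
jittered fraction (0.40 ± 0.04) of pulse pressure so `dbp < map < sbp`
holds by construction; heart rate 69 ± 12 beats/min; and per-component
device-error models (invasive − estimated) of 0.71 ± 5.95, 0.19 ± 3.78 and
2.96 ± 5.21 mmHg.

**Beat morphology.** Each beat is a raised-cosine systolic upstroke over
30 % of the cycle followed by an exponential diastolic decay with an
optional dicrotic notch; the decay rate is solved numerically (bisection
via `uniroot`, tolerance 1e-10) per beat so the sampled beat's trapezoidal
mean hits the MAP target exactly — analytic ground truth for all three
per-beat values. The foot-to-foot baseline shift completes during systole
so that diastole decays monotonically to the next foot; a linear
foot-to-foot baseline produces spurious interior diastolic minima at low
pulse pressure, which no reasonable foot detector should be asked to
survive. Beat-to-beat variability defaults to white jitter of 4.1/2.8/2.3
mmHg (SBP/MAP/DBP) — the within-recording variability of hemodynamically
stable catheter-lab recordings — with 3 % period jitter and 0.5 mmHg white
measurement noise.

**Special patients.** Deterministic counts (rounded fractions of n, 22:14:10
at the default 191) are assigned to three failure modes, so exclusion
accounting is exact under any seed:

- *Severe arrhythmia*: 40 % of beats are extrasystoles — shortened cycle
  (× 0.6) and halved pulse pressure. The 50 % reduction (the configurable
  default for sporadic ectopy is 25 %) is the generator's definition of
  *severe*: at 40 % contamination a milder reduction is not reliably
  separable from normal variability by any median-based rule, and the
  study's own exclusions were unambiguous to a human reader.
- *Hemodynamic instability*: a slow sinusoidal drift (two cycles per
  recording) in one component, amplitudes 16/10/12 mmHg for the SBP/MAP/DBP
  sub-reasons. Drift contributes A/√2 to the beat-to-beat SD
  deterministically, regardless of recording length, so short-site
  recordings fail the stability rule as reliably as long ones — inflated
  white jitter does not have this property.
- *Corrupted recording*: a −90 mmHg offset emulating a transducer zeroing
  error; the pipeline's plausibility screen (mean DBP below 30 mmHg)
  catches it before the physiologic rules run.

**Cuff recordings** deflate linearly at 4 mmHg/s from SBP + 40 mmHg down to
30 mmHg, with pulse amplitudes following a Gaussian envelope in (cuff −
MAP) of width 25 mmHg and peak 3 mmHg, plus 0.5 mmHg noise. The deflation
floor of 30 mmHg ensures the envelope falls below the diastolic ratio even
for low-MAP patients. **Flush tests** ring down from a ≥ 180 mmHg plateau
as `baseline + A·exp(−ζω_n t)·cos(ω_d t)`; their default noise is 0.1 mmHg
(QC traces are high-SNR transducer recordings; the parameter is
configurable like every other noise level, none of which are constrained
by published data).

**What passing tests show — and what they do not.** The synthetic signals
have exactly known per-beat values, stationary noise, ideal linear
deflation, a symmetric envelope and a stylized beat shape. Recovery of
ground truth on them validates the *pipeline's* correctness and its
robustness to the failure modes explicitly modelled (ectopy, drift,
offsets, steps, sampling-rate changes). It does not establish accuracy on
real arterial waveforms, whose morphology varies with age and disease,
whose envelope is asymmetric, and whose artifacts are richer than steps
and extrasystoles; nor does it validate any particular central-pressure
estimator, for which the device-error model is a stand-in.

## Problem sizes and tolerances

The test suite exercises: the full 191-patient scenario end to end in the
acceptance script; a 145-patient no-exclusion cohort for device-error
recovery (mean within 3σ/√n, SD within the two-sided 99 % χ² band);
envelope MAP recovery on 100 randomized recordings (HR 50–110, MAP 70–140,
error bound 2 mmHg); flush recovery on the 4 × 3 grid fn ∈ {15, 20, 25,
29} Hz × ζ ∈ {0.14, 0.21, 0.29} (bounds 0.5 Hz and 0.02); and brute-force
oracle equivalence for beat values and error bins on 1000 random cases.
Round-trip tolerances for beat values are 0.5/0.5/1 mmHg (SBP/DBP/MAP) on
noise-free signals; with the default 0.5 mmHg noise, per-beat extrema
acquire a small extreme-value bias that is part of what the stability SDs
measure, so exact recovery is asserted against the emitted samples rather
than the pre-noise targets.

## Known limitations

- The surrogate central estimator is intentionally naive; agreement
  statistics obtained with it characterize the pipeline, not a device.
- The ISO-2018 probability uses the normal model; heavy-tailed error
  distributions would need the empirical variant (reported alongside).
- Foot timing on real, heavily damped waveforms may need site-specific
  tuning of the upstroke threshold and refractory period; both are
  exposed as arguments.
- The generator does not model respiration, reflected-wave morphology
  changes, cuff-motion artifacts other than steps, or ECG timing; claims
  about those remain outside what the tests establish.
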