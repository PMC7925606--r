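---
title: "Tracking mean arterial pressure with the volume control technique"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking mean arterial pressure with the volume control technique}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vctbp)
```

## The measurement problem

Classic finger-cuff blood-pressure monitors use the vascular unloading
technique: a fast pneumatic servo clamps the arterial volume of a finger on
a millisecond scale, so the cuff pressure reproduces the full pulsatile
pressure waveform. The speed requirement makes such actuators power-hungry
and bulky. The volume control technique (VCT) implemented here inverts the
design: the contact pressure `p_c(t)` of a small light sensor only needs to
follow *mean* arterial pressure (mBP), which changes on the time scale of
seconds, so a slow, quantized, low-power actuator suffices. The pulsatile
waveform is recovered afterwards by superimposing the calibrated
photoplethysmographic (PPG) pulse onto the tracked mean pressure.

`vctbp` implements the complete control stack — signal decomposition,
oscillometric initialization, beat-based and continuous control,
antiresonance, and calibration — together with a synthetic
finger-hemodynamics simulator so the closed loop can be initialized, run,
stressed and evaluated entirely at desk scale. No measured data are used
anywhere; all numbers below are produced by the package itself.

## Signals and conventions

All signals are uniformly sampled at 250 Hz. The transmitted-light signal
`v(t)` is dimensionless and *inversely* related to arterial volume: rising
blood volume absorbs more light, so a blood-pressure rise lowers `v(t)` and
systole is a local *minimum* of the pulsatile component. The filter cascade
decomposes `v(t)` into

* `v_Pulse` — content above the 0.5 Hz pulse split (two cascaded
  first-order high-pass blocks);
* `v_Rhythm` — the 0.01–0.5 Hz band holding respiratory (0.15–0.4 Hz) and
  Mayer-wave (~0.1 Hz) rhythms (two-stage very-low-frequency high-pass
  followed by a four-stage low-pass);
* `v_dRhythm` — a band-limited derivative of `v_Rhythm` (first difference
  at the decimated rate, then smoothed);
* `v_VCT` — `v(t)` with content below 0.01 Hz removed but the pulses
  retained; its beat integral is the volume-balance control signal.

Every stage is the first-order IIR recursion
`y_i = (1 - UC) y_{i-1} + UC x_i`. Stages with very low cutoffs run
decimated so their update coefficients stay in a numerically comfortable
range. Two implementation details matter and were found the hard way:

* **Decimation is anti-aliased.** Each decimated stage averages its input
  block before the recursion advances. The boxcar places nulls exactly at
  multiples of the decimated rate; naive take-every-Nth decimation folds
  pulse harmonics (exactly 10 Hz at 120 bpm against the 10 Hz trend stage)
  into the very-low-frequency trend and biases the tracker by several mmHg.
* **The `v_VCT` washout is first order.** The beat-based integral
  reconstructs slow pressure changes from the washout transient, and the
  accumulated correction is proportional to the *step-response area* of the
  washout. A second-order high-pass has zero step-response area, so the
  summation would cancel itself and the controller could hold no lasting
  correction. The rhythm branch, which needs no DC memory, keeps its
  two-stage high-pass. The single washout stage is placed at 1.2x the
  nominal 0.01 Hz cut so its gain at the cutoff stays in the −3 to −5 dB
  neighbourhood.

## The simulator

The arterial waveform is a template pulse (Gaussian systolic upstroke,
exponential decay, dicrotic bump) scaled beat-by-beat to systolic and
diastolic values; the decay constant is solved once so the time average of
the normalized shape is exactly 1/3, making per-beat mean pressure equal
`dBP + PP/3`. Respiratory and Mayer modulation, step/ramp/Valsalva-like
events and a lagged vasomotor-tone trajectory shape the beat-to-beat
values. Beat-period jitter is log-normal with 2% SD.

The pressure-to-light transfer is the S-shaped arctangent

`v = v_low(tone) + (v_high - v_low(tone)) * (atan((p_c - p_a - x0)/w) + pi/2) / pi`

with the upper asymptote independent of tone and the lower asymptote rising
with vasoconstriction. The centre offset `x0` (default −6.7 mmHg, i.e. the
compliance maximum at a slightly positive transmural pressure) is the one
free asymmetry parameter of the curve, and it is not cosmetic: with a
symmetric curve (`x0 = 0`) the oscillometric amplitude maximum sits at the
systolic/diastolic *midpoint*, `mBP + PP/6`, about 6.7 mmHg above mean
pressure at a 40 mmHg pulse pressure. Choosing `x0 = -PP_ref/6` places the
amplitude maximum exactly at mean pressure — which is what the
maximum-oscillation rule empirically finds on real fingers — and keeps the
amplitude-versus-pressure curve symmetric, so the Gaussian envelope fit is
unbiased. This offset models the physiological asymmetry of the arterial
compliance curve that the empirical rule relies on.

The actuator is a slew-limited (30 mmHg/s), quantized (0.1 mmHg stepper
semantics), delayed (20 ms) follower. With quantization enabled the
internal continuous trajectory slews at 0.98x the limit so that pressure
changes over any window of half a second or longer stay within the limit,
quantization steps included; with quantization disabled the slew equals the
limit exactly.

What the simulator does *not* emulate: probe-geometry and skin-coupling
optics, ambient light, temperature drift of the PPG elements,
within-beat wave reflection changes, arrhythmia, and sensor movement other
than additive bursts. Passing the suite therefore demonstrates the control
architecture under idealized optics, not clinical accuracy.

## Initialization and the two control branches

A 0-to-200 mmHg ramp at 2 mmHg/s yields per-beat amplitude points of
`v_Pulse`; points below the 20 mmHg light-coupling floor and below 25% of
the maximum amplitude are excluded and a Gaussian `A exp(-(p-mu)^2/2s^2)`
is fitted by least squares. The peak `mu` is the mean-pressure estimate
(maximum-oscillation rule), the initial setpoint `P0`, and the anchor for
the companion light value `v0` (beat-mean light at the beat nearest `mu`).
Ratio-derived systolic/diastolic estimates use
`sBP = mu + sigma * sqrt(-2 log r_sys)` with defaults
`r_sys = 0.55, r_dia = 0.85` from the oscillometric literature; these are
UNVALIDATED placeholders for calibration only. After the ramp the actuator
descends to `P0` *before* the filter states are seeded with `v0` (the
saturated light level of the descent must not enter the washout), holds a
few seconds, and closes the loop.

Beat-based branch (per detected beat):

* `Vbar_n = (1/PI) * integral of v_VCT` over the beat — zero for a balanced
  pulse, negative for "fat" pulses (contact pressure below mean pressure),
  positive for "spiky" ones;
* `P_n = P_0 - c_BBI * sum(Vbar) - c_BBP * Vbar_n`.

Continuous branch (every sample):

* `y_PD = c_P * v_Rhythm + c_D * v_dRhythm`; `y_I = y_I + c_I * y_PD`;
* command `p_C = P_n - y_I - y_PD`, then the antiresonance notch, then
  clamping to [coupling floor, 250 mmHg] with anti-windup (the integrals
  freeze while clamped).

The compiled loop adds three refinements that the printed control law
leaves to firmware, each adopted after a measured failure:

1. **Sample-wise integral accumulation.** The running sum of per-beat
   integrals equals `(1/PI)` times the running integral of the balance
   signal; accumulating it sample-wise avoids detection-jitter at the beat
   window edges, which rectifies under rhythmic amplitude modulation and
   produced a slow drift.
2. **Pulse-free balance integrand.** The full-beat integral of `v_Pulse` is
   zero at balance, so subtracting it from `v_VCT` keeps the information
   content and removes the pulsatile edge noise.
3. **A fat/spiky shape anchor.** The washout gives the loop no absolute
   reference: any offset that survives a transient persists indefinitely,
   and a vasomotor tone ramp locked in a ~4 mmHg error. The per-beat mean
   of the linearly detrended light relative to the beat's detrended
   extremes is invariant to shifts of the lower asymptote (tone) and to
   amplitude scaling, and increases monotonically with contact pressure
   (~0.01 per mmHg at the defaults). Its deviation from the balanced value
   `S0` — self-calibrated on the first 20 s of closed-loop beats — is
   integrated slowly (gain `c_SA`) into the setpoint. This makes the
   qualitative fat/spiky mechanism an absolute anchor and reduces the tone
   ramp's steady-state error to a few tenths of a mmHg.

Robustness: the beat integral is clipped to 0.6x the running pulse
amplitude, the rhythm inputs to 0.6x (and 4x per second for the
derivative), and beats with refractory-limited intervals or exploding
amplitude are treated as motion artifacts whose integrals do not move the
setpoint. The continuous integral carries a 60 s forgetting factor
(`controller_gains(y_I_tau = )`, `Inf` disables): without it the two
integrators wind up against each other and the tracked pressure drifts.

## Antiresonance

The deliberately slow actuator reduces the loop's phase margin; with high
rhythm gain the loop oscillates at 0.1–1 Hz, typically near the breathing
band. A spectral detector (30 s window, linear detrend, periodogram peak
above 2 mmHg with at least 3 cycles and 4x median-band prominence) tunes a
constrained biquad notch — zeros on the unit circle at the detected
frequency, unity DC gain, ≥20 dB centre attenuation, within 1 dB outside
twice its bandwidth — in the command path. A notch alone proved
insufficient: a broadband marginal instability simply moves to a
neighbouring frequency, and the measured band power *increased*. The
antiresonance system therefore also backs the rhythm gains off by 0.6x on
every (re)tune (floor 0.25x). In the resonance-prone configuration
(`c_P = 200, c_I = 1e-3`) this reduces the 0.1–1 Hz band power of the
contact pressure by about 30 dB.

## Calibration, hydrostatics, operation modes

`p_C2G(t) = p_c(t) + k * v_Pulse(t)` with
`k = (sBP_init - dBP_init) / (v_sys - v_dia)`; under the inverse
light-volume convention `k < 0`, so systole maps to a pressure maximum, and
the calibration beat reproduces the calibration pulse pressure exactly.
Heart-level correction subtracts `d_v * 0.78` mmHg per cm of
finger-below-heart distance. The operation-mode machine cycles start →
initial (ramp) → measure → interpolate (pressure at the coupling floor,
mean pressure estimated by a per-session linear model on per-beat pulse
amplitude and baseline light — a deliberately simple stand-in) → back to
initial on the 13-min timer or on a pulse-morphology change. Continuous
measurement is the default for evaluation runs; the duty cycle is enabled
with `mode_schedule()`.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `c_BBI` | 60 | mmHg per volume unit | beat-based integral gain |
| `c_BBP` | 20 | mmHg per volume unit | beat-based proportional gain |
| `c_P`, `c_D` | 25, 1.2 | mmHg per volume unit | continuous rhythm gains |
| `c_I` | 4e-4 | per sample | continuous integral gain |
| `y_I_tau` | 60 | s | forgetting time of `y_I` |
| `c_SA` | 8 | mmHg per shape unit | shape-anchor integral gain |
| `cutoff_vlf`, `cutoff_pulse` | 0.01, 0.5 | Hz | band edges |
| `w`, `center_offset` | 15, −6.7 | mmHg | S-curve width and asymmetry |
| `max_rate`, `resolution` | 30, 0.1 | mmHg/s, mmHg | actuator limits |

The gains were tuned once on the standard scenario suite with
`scripts/tune_gains.R` and frozen; they are device constants, not per-run
knobs. The loop is stable for roughly `c_BBI * slope < 1` per beat, where
`slope ~ 0.012` per mmHg is the light-pressure sensitivity at the
operating point.

## Numerical choices and degenerate inputs

Envelope fitting requires ≥8 points spanning ≥40 mmHg with an interior
maximum; monotone amplitude profiles raise an "envelope not domed" error.
Beat detection uses an armed two-phase state machine (descent by 0.35x the
running amplitude arms the trough; a rise of 0.25x confirms it) with a
250 ms refractory period, which ignores dicrotic waves; flat signals yield
an empty beat table, and three seconds without a beat halve the amplitude
estimate and reset the trackers while the setpoint holds. Equal `v_sys`
and `v_dia` make the calibration scale undefined and raise a "degenerate
pulse" error. A run whose contact pressure stays pinned at a range limit
for more than 10 s is flagged `failed` rather than raising.

## What the tests do and do not show

The standard suite (ten seeded 30-min scenarios: constant, ±20 mmHg steps,
drift, respiratory-heavy, Mayer-heavy, tone ramp, combined tone and
pressure with a Valsalva-like excursion, motion artifacts, 120 bpm
tachycardia, and a hypotensive range around 55 mmHg) is evaluated with
10-s averaged tracked-versus-true pairs and repeated-measures Bland-Altman
limits of agreement, mirroring how wearable monitors are validated against
the 5 ± 8 mmHg bound of the intermittent-sphygmomanometer standard. At the
frozen defaults the suite shows a bias magnitude well under 1 mmHg and an
SD well under 2 mmHg — far inside the bound, as expected for idealized
optics and exactly matched sensor models. These numbers say the *control
architecture* is sound; they say nothing about skin optics, probe fit,
motion beyond additive bursts, or population physiology, all of which
dominate real-world error budgets.

Problem sizes used throughout (10 scenarios x 30 min x 250 Hz for the
agreement study; 100 seeded ramps for the initialization study) were chosen
as the smallest sizes at which the estimates are visibly stable across
seeds.

## Reproducing the headline numbers

```r
# full agreement study (about a quarter of a minute)
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
suite <- standard_scenarios(1800)
res <- run_closed_loop(suite$constant, seed = 1)
print(res)
pr <- tracked_pairs(res)
c(bias = mean(pr$tracked - pr$truth), sd = sd(pr$tracked - pr$truth))
```

## Known limitations

* The interpolation-mode estimator is a per-session linear model; its
  accuracy during pressure-released phases is reported, not guaranteed.
* The resonance detector cannot distinguish loop resonance from a genuine
  blood-pressure rhythm at the same frequency; once the notch engages, the
  contact pressure intentionally stops following that band (the calibrated
  waveform still carries it). Rhythm-heavy scenarios therefore show the
  largest residual biases (~2–3 mmHg).
* Ratio-derived systolic/diastolic values are calibration placeholders.
* The shape anchor assumes the S-curve's asymmetry parameter is constant
  within a session; slow drifts of `w` or of the centre offset would be
  absorbed only at the next re-initialization.
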