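---
title: "Pulse decomposition analysis: model, algorithm and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse decomposition analysis: model, algorithm and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsedecomp)
```

## The physical picture

The arterial pressure pulse observed at the radial or digital artery is not
a single wave.  The left-ventricular ejection pulse (#1) travels down the
aorta and meets two strong impedance mismatches: the junction of thoracic
and abdominal aorta near the renal arteries, and the junction of abdominal
aorta and common iliac arteries.  Each reflects part of the pulse back up
the aorta and into the subclavian/arm arteries, so the peripheral pulse
envelope is a superposition of the primary pulse, a "renal" reflection
(#2) arriving roughly 70--140 ms later, an "iliac" reflection (#3)
arriving 180--400 ms later, and two re-reflections of rapidly diminishing
amplitude (#4, #5).

Two beat-level parameters summarize the envelope:

* **T13** -- the delay between the #1 and #3 component peaks.  Because the
  two pulses load the arterial wall at different pressures, their speeds
  respond differently to a change in blood pressure, and T13 tracks pulse
  pressure beat by beat.
* **P2P1** -- the amplitude ratio of the #2 and #1 components.  The renal
  reflection coefficient grows with systolic pressure (the compliant
  thoracic aorta dilates against the stiffer abdominal aorta), so P2P1
  tracks systolic pressure.

## The forward model

Each component pulse accumulates travel time over its path legs,

$$t_1 = \frac{x_1}{\nu_{x1}(P_{11})},\qquad
  t_2 = \frac{x_2}{\nu_{x2}(P_{21})} + \frac{x_2}{\nu_{x2}(P_{22})} +
        \frac{x_1}{\nu_{x1}(P_{23})},$$

and analogously five legs for $t_3$, with leg pressures built from the
reflection cascade (a reflected pulse carries diastole plus the reflection
coefficient times pulse pressure, and loses a factor $(1-R)$ through each
site it crosses).  Wave speed follows the pressure-dependent
Moens--Korteweg relation

$$\nu(P) = \sqrt{\frac{h\,E\,e^{\zeta P}}{2\rho\alpha}},$$

with wall thickness $h$, Young's modulus $E$, diameter $\alpha$, blood
density $\rho$ and a compliance exponent $\zeta$ in 1/mmHg.  Pressures are
mmHg throughout; delays are reported in ms.

**Response shapes.** The velocity of the muscular arm arteries responds
exponentially to pressure, while the central (elastic) aortic segments are
modelled with the first-order expansion of the same law about 90 mmHg.
This asymmetry is not cosmetic: it is the combination under which T13
*shortens* as diastole rises toward a fixed systole in the 60--100 mmHg
regime — the behaviour seen during central hypovolemia, where pulse
pressure falls through rising diastole at constant systole.  With a single
global exponential response the predicted T13 slope has the wrong
magnitude profile.

**Default calibration.** Defaults are effective lumped-path values for a
young-adult cohort of average height ~1.69 m, chosen once against three
anchors: the thoracic aorta is the slowest segment (4--5 m/s at 80 mmHg),
peripheral speeds stay within the physiological 4--9 m/s band, and the
predicted delays at 120/80 mmHg fall inside the observed windows
(`arrival_times(pressure_state(120, 80))` gives T12 = 126.7 ms,
T13 = 205.1 ms).  The segment *lengths* (0.80 m arm, 0.26 m thoracic,
0.28 m abdominal) are effective lengths of a three-path lumped model, not
anatomical tape measurements; no published lengths exist for the model's
path decomposition, and the in-band thoracic speed forces a thoracic path
somewhat shorter than the often-quoted 0.35 m.  Reflection coefficients
default to $R_1 = 0.10$ (arm-entry transmission loss, unquantified in the
literature, kept small and configurable), $R_2 = 0.17$ at 120 mmHg with a
configurable affine pressure slope of 0.002/mmHg (the functional form of
the pressure dependence is not established; affine-with-clamping is the
minimal choice), and $R_3 = 0.40$.

```{r curve}
t13_pressure_curve(seq(60, 100, 10), systole = 120)
```

## The synthesizer: a stated world

`synthesize_session()` emulates what the sensor sees: a 512 Hz stream that
is the *time derivative* of the pressure waveform (the first difference
scaled by the sampling rate, so cumulative summation recovers the pressure
waveform exactly on noise-free input), with additive white Gaussian noise
(default sd 2% of the primary derivative amplitude).

Each beat is a superposition of five unimodal kernels — two-sided
Gaussians with width 60 ms (FWHM) and skew 0.3, a steep-rise/slow-decay
shape matching rounded arterial pulses without overcommitting to an
unstated line shape.  Component delays come from the forward model, so the
per-beat ground truth equals the model's T12/T13 *exactly*; amplitudes
default to 0.30, 0.40, 0.08, 0.02 of the primary (an iliac reflection of
20--40% of the primary, re-reflections fading fast).  Kernels are
evaluated continuously at the sample instants: peaks sit at their delays
with sub-sample accuracy, so the ground truth is not quantized to the
sampling grid.  (An earlier grid-rounded implementation quantized truth by
up to ±1 sample per component and contaminated closed-loop bias
estimates.)

The LBNP schedule applies, per stage (0, −15, −30, −45, −60 mmHg),
diastole shifts of +0, +2, +4, +6, +8 mmHg at fixed systole and heart-rate
shifts of +0, +2, +5, +12, +25 bpm.  Rising diastole at fixed systole is
what a falling pulse pressure driven entirely by diastole means; it also
produces the stage-over-stage T13 *shortening* that the model predicts and
the chamber studies observe.  Both mappings are per-subject scalable
(responsiveness multipliers) and configurable; they are plausibility
defaults, not dose-response claims.  Stage durations default to 30 s — a
scaled-down stand-in for the roughly 12-minute chamber stages — which
keeps desk-scale sessions around 150 s of signal while still averaging
~30 beats per stage.

What the generator deliberately does **not** model: respiration and motion
artifact, vasomotor drift of the peripheral coupling, the post-vent
augmentation rebound, presyncope, and any extra reflection sites.  A green
closed-loop test therefore establishes that the *algorithm* recovers known
component timing under realistic noise and heart-rate variation — not that
the device-side physics is solved.

## The extraction algorithm

1. **Beat finding** on the derivative stream: candidate peaks on an 8 Hz
   low-passed copy must exceed 40% of the median one-second block maximum
   and respect a 300 ms refractory interval; the onset is the zero
   crossing preceding the maximal positive excursion, refined on the raw
   stream (the smoothed crossing alone sits early by the filter's
   backward spread).
2. **Integration**: cumulative sum, a first-order 0.3 Hz high-pass (noisy
   input would otherwise random-walk), and a 4th-order 15 Hz Bessel
   low-pass, all zero-phase.  The Bessel family's flat group delay is why
   it is the canonical integrator choice for pulse analysis.
3. **Component location**: the primary peak is identified on an 8 Hz
   low-passed copy of the beat, then *timed* as the nearest inversion
   (local minimum) of the second derivative; P2 and P3 are the earliest
   qualifying inversions inside the 70--140 ms and 180--400 ms windows
   after P1.  Timing all three components in the same second-derivative
   frame makes their shared bias cancel in T12/T13 (measuring P1 on the
   waveform maximum instead leaves a ~5 ms frame mismatch).  Inversions
   must reach 2% of the beat's peak curvature — without a prominence
   floor, filtering ripple in an empty window produces phantom
   components.  Sub-sample timing uses parabolic interpolation;
   amplitudes are read off the integrated waveform against the onset
   baseline.
4. **Metrics**: T13, P2P1, augmentation index
   $(P_2 - P_1)/\text{envelope}$, and the SDPTG $d/a$ ratio from the a--e
   wave labelling of the second derivative (alternating extrema from the
   first maximum).
5. **S/N gate**: ratio of 0.5--15 Hz to out-of-band power per 2 s block,
   capped at 60 dB, gate at 10 dB.  Note that a clean pulse still has
   harmonic content above 15 Hz, so the noise-free figure is ~14 dB, not
   the cap; the cap is reached only by band-limited input.  Blocks that
   fail the gate are excluded from component analysis.

Missing components are reported as `NA` and flag the beat invalid —
metrics are never fabricated.  All windows, cutoffs and thresholds are
`extract_opts()` parameters; the defaults above are design choices where
the algorithm description names only the filter family or the idea.

```{r loop}
ses <- synthesize_session(session_spec(seed = 1))
ex <- extract_beats(ses)
ex$quality
```

## Cohort statistics

`stage_aggregate()` maps beats to stages and produces subject-by-stage
means; `fit_linear()`/`fit_quadratic()` are plain OLS (T13 relates
linearly to pulse pressure but needs a quadratic term against heart
rate); `rm_anova()` is a one-way within-subject ANOVA (joint stage factor,
or baseline-versus-pooled-stages; optional Greenhouse--Geisser
correction, off by default as the minimal reading of the published
analysis); `roc_stage()` discriminates two stages through their
per-subject deltas from the atmospheric baseline, with the AUC as the
rank statistic of the two delta samples.

The stage-level cohort simulator draws per-subject baselines (diastole
$N(80, 4)$ truncated to 72--88 mmHg, heart rate $N(65, 7)$) and instrument
readings: T13 stage means carry 0.3 ms extraction error (beat jitter
averaged over a stage), automatic-cuff pulse pressure is the mean of 4
readings with sd 20 mmHg each, and the continuous finger monitor has a
stage-mean sd of 8 mmHg.  The PP noise scales were set from the published
cohort numbers — a reported standard error of ~3.5 mmHg on a 15-subject
mean implies a per-subject-stage sd above 10 mmHg, and the finger
instrument showed no discernible LBNP trend at all.  An earlier, kinder
parametrization (cuff stage-mean sd 5 mmHg) let the cuff resolve the
−15/−30 mmHg stages, which inverts the qualitative instrument ranking the
validation is supposed to mirror; the recalibration is recorded in the
decisions ledger.  Under this world T13 resolves the two mildest stages
at $p < 0.01$ while the cuff does not, and AUC(T13) ≈ 0.96 ≫ AUC(cuff) ≈
0.5 — a scaled-down qualitative reproduction of the published instrument
comparison, not of its exact numbers (the recordings were never
deposited, so $-72$ ms, $R^2 = 0.98$, AUC 0.83 and the Table 1 p-values
are out of reproduction scope by design).

## Numerical choices and degenerate inputs

* Filters are designed in-package (bilinear transform of the analog
  prototypes with frequency pre-warping) because no filter-design package
  is assumed; coefficients are pinned in tests against an independent
  reference implementation to 1e-10.
* Zero pulse pressure is not a valid `pressure_state` (systole must
  exceed diastole); the all-pressures-equal limit is exercised at
  PP = 1e-9 mmHg.
* A linear-response segment whose expansion would cross zero velocity
  raises an error rather than returning nonsense.
* Ties among second-derivative inversions resolve to the earliest
  qualifying one; sub-sample offsets are clamped to ±0.5 samples.
* `rm_anova` returns p = 1 when the stage sum of squares vanishes and the
  smallest representable p when the error stratum vanishes, keeping p in
  (0, 1].
* Incomplete designs (e.g. presyncopal subjects missing the −60 mmHg
  stage) are handled by listwise deletion with a warning.
* Determinism: one seed drives a session; cohort loops derive per-subject
  sub-seeds (a fixed LCG step, kept below 2^31) so results are
  bit-reproducible and independent of evaluation order.

## Known limitations

* The model is a three-path lumped approximation; segment parameters are
  effective values, and the renal coefficient's pressure slope is a
  configurable placeholder, not a measured quantity.
* The synthesizer's kernel family is an assumption; real component-pulse
  line shapes vary between subjects and with vasomotor state.
* The S/N figure of merit and the Bessel integrator specification are
  package design choices exposed in `extract_opts()`, not claims of
  fidelity to any commercial device.
* At heart rates above ~100 bpm the late re-reflections spill into the
  following beat (as they do physiologically); ground truth for
  components 4--5 is then approximate, which is one reason they are not
  analyzed.
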