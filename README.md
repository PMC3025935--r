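# pulsedecomp

Pulse Decomposition Analysis (PDA) of the peripheral arterial pressure
pulse, in R.

## The problem

Detecting progressive hemorrhage needs resolution of pulse-pressure
changes of a few mmHg — beyond what cuffs can deliver.  PDA offers a
beat-by-beat surrogate: the peripheral (radial/digital) pulse is treated
as the superposition of the primary left-ventricular ejection pulse (#1)
and reflections from two central arterial sites — the thoracic/abdominal
aortic junction near the renal arteries (#2, "renal reflection") and the
aorto-iliac junction (#3, "iliac reflection") — plus two faint
re-reflections.  Because the #1 and #3 pulses ride at different pressures,
their Moens–Korteweg wave speeds

$$\nu(P) = \sqrt{h E\, e^{\zeta P} / (2 \rho \alpha)}$$

respond differently to blood-pressure changes, so the #1→#3 delay **T13**
tracks pulse pressure, and the amplitude ratio **P2P1** tracks systolic
pressure.

The package implements, as separate but composable modules:

* **Forward model** — component-pulse pressures from the reflection
  cascade, pressure-dependent wave speeds (exponential arm response,
  linearized central response), arrival times t1, t2, t3 and the delays
  T12/T13 (`arrival_times()`, `t13_pressure_curve()`).
* **Waveform synthesizer** — ground-truthed 512 Hz sensor-derivative
  streams with five-component beats, LBNP stage schedules (0 to −60 mmHg),
  heart-rate drift and additive noise (`synthesize_session()`).
* **Extractor** — the pulse decomposition algorithm: beat finding on the
  derivative stream, Bessel-filter integration, component location via
  second-derivative inversions inside the physiological windows
  (70–140 ms, 180–400 ms), S/N gating; per beat T13, P2P1, augmentation
  index and SDPTG d/a (`extract_beats()`).
* **Cohort statistics** — stage aggregation, linear/quadratic fits,
  repeated-measures ANOVA and ROC stage discrimination
  (`rm_anova()`, `roc_stage()`).
* **Config & CLI** — JSON run configuration, deterministic seeded
  pipeline, `pulsedecomp simulate|extract|analyze|fitcurve|run`
  (`inst/exec/pulsedecomp`, `run_pipeline()`).

## Worked example

Forward model at the representative 120/80 mmHg state:

```r
library(pulsedecomp)
arrival_times(pressure_state(120, 80))
#> <arrival_times t1=89.1 ms t2=215.7 ms t3=294.2 ms | T12=126.7 ms T13=205.1 ms>
```

The renal delay (126.7 ms) and iliac delay (205.1 ms) fall inside the
observed 70–140 ms and 180–400 ms windows.  Closed loop — synthesize an
LBNP session (five stages, rising diastole at fixed systole, default 2%
noise), run the extractor, and aggregate by stage:

```r
ses <- synthesize_session(session_spec(seed = 1))
ex  <- extract_beats(ses)
ex$quality
#> $beats_detected                 [1] 188
#> $component_detection_efficiency [1] 1
#> $snr_db_median                  [1] 12.3
#> $beats_expected                 [1] 188
#> $beat_detection_efficiency      [1] 1

stage_aggregate(ex$beats, default_lbnp_stages())[, c(2, 3, 4, 5)]
#>   lbnp n_beats T13_mean  T13_se
#> 1    0      30    205.9 0.05481
#> 2  -15      34    204.2 0.06038
#> 3  -30      26    202.4 0.06690
#> 4  -45      38    200.6 0.07342
#> 5  -60      44    198.9 0.08755
```

Every beat was detected and decomposed; the extracted per-stage mean T13
shortens monotonically with LBNP depth and sits within ~0.9 ms of the
synthesizer's ground truth (205.1, 203.3, 201.5, 199.7, 197.9 ms) — the
pulse narrows as simulated central blood loss lowers pulse pressure.  On a
15-subject summary cohort the stage effect on T13 is unambiguous while the
noisy cuff channel is not:

```r
st <- simulate_stage_cohort(n_subjects = 15, seed = 2)
rm_anova(st, "T13_mean", stages = c(0, -15, -30))$p_value
#> [1] 5.18e-20
```

## Documentation

The methods vignette (`vignettes/pulse-decomposition.Rmd`) documents the
model assumptions, the synthesizer's stated world and its limits, the
extractor's numerical choices, and the statistical design.
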