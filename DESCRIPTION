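Package: pulsedecomp
Title: Pulse Decomposition Analysis of Peripheral Arterial Pressure Waveforms
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward modelling and beat-level analysis of the peripheral
    arterial pressure pulse treated as a superposition of a primary
    ejection pulse and reflections from two central arterial sites (the
    renal and iliac reflection sites). Provides a Moens-Korteweg based
    forward model with pressure-dependent wave speeds that predicts
    component-pulse arrival times (T12, T13), a ground-truthed 512 Hz
    sensor-derivative waveform synthesizer with lower body negative
    pressure (LBNP) stage schedules, a pulse decomposition extractor that
    segments beats, integrates the derivative stream and locates component
    pulses via second-derivative inversions (reporting T13, P2P1, the
    augmentation index and the SDPTG d/a ratio), and cohort statistics
    (stage aggregation, regressions, repeated-measures ANOVA, ROC) used to
    evaluate T13 as a pulse-pressure surrogate during simulated central
    hypovolemia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
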