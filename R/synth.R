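# Ground-truthed waveform synthesis.
#
# Emulates the sensor-side view of the arterial pulse: a 512 Hz stream that
# is the time derivative of the pressure waveform, where each beat is the
# superposition of five unimodal component pulses (primary ejection, renal
# reflection, iliac reflection and two re-reflections of rapidly diminishing
# amplitude).  Component delays are taken from the forward model so each
# synthesized beat carries exact ground truth for closed-loop testing of the
# extractor.

#' Unit-peak component-pulse kernel
#'
#' A single-maximum, non-negative line shape used for each component pulse.
#' The kernel is a two-sided Gaussian: the left/right standard deviations
#' are `sd / (1 + skew)` and `sd * (1 + skew)` with
#' `sd = width / (2 sqrt(2 log 2))` so that `width` is approximately the
#' full width at half maximum in ms.  `skew = 0` gives a symmetric kernel;
#' positive skew yields the steep-rise/slow-decay asymmetry of arterial
#' pulses.
#'
#' @param width kernel width (ms), must span at least 4 samples.
#' @param skew dimensionless skew >= 0.
#' @param sample_rate sampling rate in Hz.
#' @return numeric vector with peak value 1; attributes `peak` (1-based
#'   index of the designed peak sample) and `peak_offset_ms` (designed peak
#'   time relative to kernel start).
#' @export
component_kernel <- function(width, skew = 0, sample_rate = 512) {
  check_scalar(width, "width", 0, strict_lower = TRUE)
  check_scalar(skew, "skew", 0)
  check_scalar(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  if (width * sample_rate / 1000 < 4)
    stop_invalid("kernel width ", width, " ms is below the 4-sample ",
                 "resolution limit at ", sample_rate, " Hz")
  sd <- width / (2 * sqrt(2 * log(2)))
  sd_l <- sd / (1 + skew)
  sd_r <- sd * (1 + skew)
  ## snap the peak to the sampling grid: the sampled kernel then attains
  ## exactly 1 and a skew-0 kernel is exactly symmetric about its argmax
  t_pk <- round(3.5 * sd_l * sample_rate / 1000) * 1000 / sample_rate
  t_end <- t_pk + 3.5 * sd_r
  n <- max(5L, ceiling(t_end * sample_rate / 1000) + 1L)
  t <- (seq_len(n) - 1L) * 1000 / sample_rate
  k <- kernel_value(t - t_pk, sd_l, sd_r)
  k <- k / max(k)
  structure(k, peak = which.max(k), peak_offset_ms = t_pk)
}

## Continuous kernel line shape evaluated at dt ms from the peak.
kernel_value <- function(dt, sd_l, sd_r) {
  s <- ifelse(dt <= 0, sd_l, sd_r)
  v <- exp(-0.5 * (dt / s)^2)
  v[dt < -3.5 * sd_l | dt > 3.5 * sd_r] <- 0
  v
}

#' Component set derived from the forward model
#'
#' Builds the five-component description of one beat.  Delays of components
#' 2 and 3 are the model's T12 and T13; the re-reflections 4 and 5 repeat
#' the iliac-renal round-trip spacing `T13 - T12`.  The first component's
#' delay is chosen so that its rise starts exactly at beat onset.
#'
#' @param state a [pressure_state()] giving the beat's ground-truth pressures.
#' @param segments,coeffs forward-model parameters.
#' @param amplitudes amplitudes of the five components as fractions of the
#'   primary amplitude (first entry must be 1); defaults reflect a renal
#'   reflection near 30% and an iliac reflection near 40% of the primary,
#'   with re-reflections of 8% and 2%.
#' @param width,skew kernel shape shared by all components (ms /
#'   dimensionless).
#' @return data.frame with columns `delay`, `amplitude`, `width`, `skew`
#'   (one row per component, delays strictly increasing, in ms from onset).
#' @export
component_set <- function(state, segments = default_segments(),
                          coeffs = reflection_coefficients(),
                          amplitudes = c(1.0, 0.30, 0.40, 0.08, 0.02),
                          width = 60, skew = 0.3) {
  if (length(amplitudes) != 5L || amplitudes[1] != 1)
    stop_invalid("amplitudes must be five values with amplitudes[1] == 1")
  if (any(amplitudes <= 0 | amplitudes > 1.5))
    stop_invalid("amplitudes must lie in (0, 1.5]")
  at <- arrival_times(state, segments, coeffs)
  sd_l <- width / (2 * sqrt(2 * log(2))) / (1 + skew)
  d1 <- 3.5 * sd_l                       # rise starts at beat onset
  echo <- at$T13 - at$T12                # iliac<->renal round trip spacing
  delays <- d1 + c(0, at$T12, at$T13, at$T13 + echo, at$T13 + 2 * echo)
  data.frame(delay = delays, amplitude = amplitudes,
             width = width, skew = skew)
}

#' Specification of one synthetic beat
#'
#' @param period inter-beat interval (ms).
#' @param components data.frame as returned by [component_set()]; delays in
#'   ms from onset, strictly increasing.
#' @param state the ground-truth [pressure_state()] of the beat.
#' @return object of class `beat_spec`.
#' @export
beat_spec <- function(period, components, state) {
  check_scalar(period, "period", 0, strict_lower = TRUE)
  stopifnot(is.data.frame(components),
            all(c("delay", "amplitude", "width", "skew") %in% names(components)))
  if (any(diff(components$delay) <= 0))
    stop_invalid("component delays must be strictly increasing")
  if (any(components$amplitude <= 0 | components$amplitude > 1.5))
    stop_invalid("component amplitudes must lie in (0, 1.5]")
  if (any(components$width <= 0)) stop_invalid("component widths must be > 0")
  ## Spill of the late re-reflections (components 4-5) into the next beat
  ## is physiological at high heart rates and silently truncated; spill of
  ## an analyzed component (1-3) invalidates the ground truth, so warn.
  k <- min(3L, nrow(components))
  if (components$delay[k] + 3 * components$width[k] >= period)
    warning("an analyzed component's tail extends beyond the beat period")
  structure(list(period = period, components = components, state = state),
            class = "beat_spec")
}

#' Synthesize the pressure waveform of one beat
#'
#' Sum of scaled, delayed component kernels.  Each component's continuous
#' line shape is evaluated directly at the sample instants, so its peak
#' sits at the specified delay with sub-sample accuracy (the ground truth
#' is not quantized to the sampling grid).  The output covers one
#' inter-beat interval and has unit primary amplitude.
#'
#' @param spec a [beat_spec()].
#' @param sample_rate sampling rate in Hz.
#' @return numeric vector of `round(period * sample_rate / 1000)` samples.
#' @export
synthesize_beat <- function(spec, sample_rate = 512) {
  if (!inherits(spec, "beat_spec")) stop_invalid("spec must be a beat_spec")
  cmp <- spec$components
  if (any(diff(cmp$delay) * sample_rate / 1000 < 1))
    stop_invalid("component delays closer than one sample period")
  n <- round(spec$period * sample_rate / 1000)
  t <- (seq_len(n) - 1L) * 1000 / sample_rate
  y <- numeric(n)
  for (i in seq_len(nrow(cmp))) {
    sd <- cmp$width[i] / (2 * sqrt(2 * log(2)))
    sd_l <- sd / (1 + cmp$skew[i])
    sd_r <- sd * (1 + cmp$skew[i])
    y <- y + cmp$amplitude[i] * kernel_value(t - cmp$delay[i], sd_l, sd_r)
  }
  y
}

#' Default LBNP stage schedule
#'
#' Five stages: atmospheric baseline then four negative-pressure stages.
#' The hemodynamic mapping emulates the observed response to progressive
#' central hypovolemia with systole held fixed: pulse pressure falls because
#' diastole rises stage over stage (shifts of +0, +2, +4, +6, +8 mmHg) while
#' heart rate climbs (+0, +2, +5, +12, +25 bpm).  Stage durations default to
#' 30 s, a scaled-down version of the roughly 12-minute stages used in the
#' chamber protocol, so that desk-scale sessions stay small.
#'
#' @param duration_s duration of every stage in seconds.
#' @param diastole_shift,hr_shift per-stage shifts (mmHg / bpm).
#' @return data.frame with columns `lbnp`, `duration_s`, `diastole_shift`,
#'   `hr_shift`.
#' @export
default_lbnp_stages <- function(duration_s = 30,
                                diastole_shift = c(0, 2, 4, 6, 8),
                                hr_shift = c(0, 2, 5, 12, 25)) {
  data.frame(lbnp = c(0, -15, -30, -45, -60),
             duration_s = duration_s,
             diastole_shift = diastole_shift,
             hr_shift = hr_shift)
}

#' Session specification for the waveform synthesizer
#'
#' @param stages stage schedule, see [default_lbnp_stages()]; `lbnp` values
#'   must come from \{0, -15, -30, -45, -60\} and durations must be positive.
#' @param sample_rate sampling rate (Hz), default 512.
#' @param noise_sd additive white Gaussian noise on the derivative stream,
#'   as a fraction of the primary derivative amplitude (default 0.02).
#' @param seed integer seed; identical seeds give bitwise-identical streams.
#' @param base_state baseline [pressure_state()] at atmospheric pressure.
#' @param base_hr baseline heart rate (bpm).
#' @param hr_jitter_sd beat-to-beat heart-rate jitter (bpm, sd).
#' @param amplitudes,width,skew component shape, see [component_set()].
#' @return object of class `session_spec`.
#' @export
session_spec <- function(stages = default_lbnp_stages(), sample_rate = 512,
                         noise_sd = 0.02, seed = 1,
                         base_state = pressure_state(120, 80),
                         base_hr = 65, hr_jitter_sd = 1,
                         amplitudes = c(1.0, 0.30, 0.40, 0.08, 0.02),
                         width = 60, skew = 0.3) {
  stopifnot(is.data.frame(stages), nrow(stages) >= 1L)
  if (!all(c("lbnp", "duration_s", "diastole_shift", "hr_shift") %in% names(stages)))
    stop_invalid("stages must have columns lbnp, duration_s, diastole_shift, hr_shift")
  if (!all(stages$lbnp %in% c(0, -15, -30, -45, -60)))
    stop_invalid("stage lbnp values must come from {0, -15, -30, -45, -60}")
  if (any(stages$duration_s <= 0)) stop_invalid("stage durations must be > 0")
  check_scalar(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(base_hr, "base_hr", 20, 220)
  check_scalar(hr_jitter_sd, "hr_jitter_sd", 0)
  structure(list(stages = stages, sample_rate = sample_rate,
                 noise_sd = noise_sd, seed = seed, base_state = base_state,
                 base_hr = base_hr, hr_jitter_sd = hr_jitter_sd,
                 amplitudes = amplitudes, width = width, skew = skew),
            class = "session_spec")
}

#' Synthesize a sensor-derivative session with ground truth
#'
#' Concatenates model-linked beats over the stage schedule, then emits the
#' first difference of the pressure waveform scaled by the sample rate (the
#' sensor observes the time derivative of the arterial pulse) plus white
#' Gaussian noise.  `cumsum(stream) / sample_rate` recovers the pressure
#' waveform exactly when `noise_sd = 0`.
#'
#' Per stage, the pressure state is the baseline with the stage's diastole
#' shift applied (systole fixed); component delays come from
#' [arrival_times()] so the per-beat ground truth `t13_ms` equals the
#' model's T13 exactly.  Beat amplitude scales with pulse pressure
#' (PP / 40), emulating the diminishing pulse at deep negative pressures.
#'
#' @param spec a [session_spec()].
#' @param segments,coeffs forward-model parameters linking stages to delays.
#' @return list of class `synth_session` with elements `stream` (a
#'   [derivative_stream()]) and `truth` (data.frame: `beat`, `onset_sample`,
#'   `onset_s`, `lbnp`, `period_ms`, `t12_ms`, `t13_ms`, `p2p1`, `p3p1`,
#'   `psyst`, `pdiast`).
#' @export
synthesize_session <- function(spec, segments = default_segments(),
                               coeffs = reflection_coefficients()) {
  if (!inherits(spec, "session_spec")) stop_invalid("spec must be a session_spec")
  fs <- spec$sample_rate
  with_seed(spec$seed, {
    wave <- list()
    truth <- list()
    onset <- 0L   # samples synthesized so far
    beat_i <- 0L
    for (s in seq_len(nrow(spec$stages))) {
      st <- spec$stages[s, ]
      state <- pressure_state(spec$base_state$Psyst,
                              spec$base_state$Pdiast + st$diastole_shift)
      cmp <- component_set(state, segments, coeffs,
                           amplitudes = spec$amplitudes,
                           width = spec$width, skew = spec$skew)
      at <- arrival_times(state, segments, coeffs)
      hr <- spec$base_hr + st$hr_shift
      stage_samples <- round(st$duration_s * fs)
      done <- 0L
      while (done < stage_samples) {
        beat_hr <- max(25, hr + stats::rnorm(1, 0, spec$hr_jitter_sd))
        period <- 60000 / beat_hr
        bs <- beat_spec(period, cmp, state)
        y <- synthesize_beat(bs, fs) * (state$PPulse / 40)
        beat_i <- beat_i + 1L
        truth[[beat_i]] <- data.frame(
          beat = beat_i, onset_sample = onset + 1L, onset_s = onset / fs,
          lbnp = st$lbnp, period_ms = length(y) * 1000 / fs,
          t12_ms = at$T12, t13_ms = at$T13,
          p2p1 = spec$amplitudes[2], p3p1 = spec$amplitudes[3],
          psyst = state$Psyst, pdiast = state$Pdiast)
        wave[[beat_i]] <- y
        onset <- onset + length(y)
        done <- done + length(y)
      }
    }
    x <- unlist(wave, use.names = FALSE)
    d <- diff(c(0, x)) * fs
    if (spec$noise_sd > 0)
      d <- d + stats::rnorm(length(d), 0, spec$noise_sd * max(abs(d)))
    structure(list(stream = derivative_stream(d, fs),
                   truth = do.call(rbind, truth), spec = spec),
              class = "synth_session")
  })
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("<synth_session: %d beats, %.1f s at %g Hz, %d stage(s)>\n",
              nrow(x$truth), length(x$stream$samples) / x$stream$sample_rate,
              x$stream$sample_rate, nrow(x$spec$stages)))
  invisible(x)
}
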