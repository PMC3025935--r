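# Shared fixtures, all built in code.

# Segments with pressure-independent wave speed of exactly 5 m/s:
# h*E/(2*rho*alpha) = 0.001 * 5.25e5 / (2 * 1050 * 0.01) = 25.
const_speed_segments <- function(x1 = 0.8, x2 = 0.35, x3 = 0.25) {
  mk <- function(name, len)
    arterial_segment(name, len, wall_thickness = 0.001,
                     youngs_modulus = 5.25e5, diameter = 0.01,
                     fluid_density = 1050, compliance_exponent = 0)
  list(arm_x1 = mk("arm_x1", x1), thoracic_x2 = mk("thoracic_x2", x2),
       abdominal_x3 = mk("abdominal_x3", x3))
}

# One-stage stationary session spec.
flat_session <- function(duration_s = 15, seed = 3, noise_sd = 0,
                         sample_rate = 512, diastole = 80, hr = 65) {
  session_spec(stages = data.frame(lbnp = 0, duration_s = duration_s,
                                   diastole_shift = diastole - 80,
                                   hr_shift = 0),
               sample_rate = sample_rate, noise_sd = noise_sd, seed = seed,
               base_state = pressure_state(120, diastole), base_hr = hr,
               hr_jitter_sd = 0)
}

# Match each truth beat to the nearest detected beat row.
match_truth <- function(beats, truth) {
  idx <- vapply(truth$onset_sample,
                function(o) which.min(abs(beats$onset_sample - o)),
                integer(1))
  beats[idx, ]
}
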