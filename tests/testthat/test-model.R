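# Forward model: wave speeds, reflection coefficients, component
# pressures, arrival times.

test_that("wave_speed matches hand arithmetic and honors the exponent", {
  seg <- arterial_segment("arm_x1", 0.8, wall_thickness = 0.001,
                          youngs_modulus = 4.0e5, diameter = 0.01,
                          fluid_density = 1050, compliance_exponent = 0)
  # sqrt(h E / (2 rho alpha)) = sqrt(400 / 21)
  expect_equal(wave_speed(seg, 100), sqrt(400 / 21), tolerance = 1e-12)
  # zeta = 0: pressure-independent
  expect_identical(wave_speed(seg, 80), wave_speed(seg, 120))

  # strictly increasing in pressure when zeta > 0, for both responses
  for (resp in c("exponential", "linear")) {
    s <- arterial_segment("thoracic_x2", 0.3, 0.001, 4e5, 0.01,
                          compliance_exponent = 0.01, response = resp)
    v <- wave_speed(s, seq(40, 200, by = 5))
    expect_true(all(diff(v) > 0), info = resp)
  }
})

test_that("default thoracic speed at 80 mmHg lies in the printed 4-5 m/s band", {
  v <- wave_speed(default_segments()$thoracic_x2, 80)
  expect_gte(v, 4)
  expect_lte(v, 5)
})

test_that("linear response is affine in pressure over [40, 200] mmHg", {
  s <- default_segments()$thoracic_x2
  p <- seq(40, 200, by = 10)
  v <- wave_speed(s, p)
  fit <- stats::lm(v ~ p)
  expect_lt(max(abs(stats::resid(fit))), 1e-10)
})

test_that("wave_speed validates its inputs", {
  expect_error(arterial_segment("arm_x1", 0.8, -0.001, 4e5, 0.01),
               "wall_thickness")
  expect_error(wave_speed(default_segments()$arm_x1, 10), "range")
})

test_that("renal reflection coefficient is affine, clamped, default 0.17", {
  expect_equal(renal_reflection_coefficient(120), 0.17)
  cf0 <- reflection_coefficients(R2_slope = 0)
  expect_equal(renal_reflection_coefficient(200, cf0), 0.17)
  cf <- reflection_coefficients(R2_at_ref = 0.17, R2_slope = 0.002)
  expect_equal(renal_reflection_coefficient(140, cf), 0.21, tolerance = 1e-12)
  # non-decreasing with positive slope; clamped inside (0, 1)
  r <- renal_reflection_coefficient(seq(60, 250, by = 5), cf)
  expect_true(all(diff(r) >= 0))
  big <- reflection_coefficients(R2_at_ref = 0.9, R2_slope = 0.05)
  expect_lt(renal_reflection_coefficient(250, big), 1)
  expect_gt(renal_reflection_coefficient(60, big), 0)
})

test_that("component pressures implement the reflection cascade", {
  st <- pressure_state(120, 80)
  cf <- reflection_coefficients(R1 = 0.1, R2_at_ref = 0.17, R2_slope = 0,
                                R3 = 0.4)
  p <- component_pressures(st, cf)
  # hand arithmetic: P33 = 80 + 0.4*0.83*40; P35 = 80 + 0.4*0.83^2*0.9*40
  expect_equal(unname(p["P33"]), 80 + 0.4 * 0.83 * 40, tolerance = 1e-12)
  expect_equal(unname(p["P35"]), 80 + 0.4 * 0.83^2 * 0.9 * 40,
               tolerance = 1e-12)
  expect_equal(unname(p["P21"]), 120)
  expect_equal(unname(p["P31"]), 120)
})

test_that("zero pulse pressure collapses every component pressure", {
  # PPulse = 0 is not a valid pressure_state; approach the limit instead
  st <- pressure_state(100 + 1e-9, 100)
  p <- component_pressures(st)
  expect_true(all(abs(p - 100) < 1e-6))
})

test_that("component pressures stay inside [diastole, systole] (property)", {
  set.seed(42)
  for (i in 1:200) {
    d <- runif(1, 50, 100)
    s <- d + runif(1, 20, 80)
    cf <- reflection_coefficients(R1 = runif(1, 0, 0.5),
                                  R2_at_ref = runif(1, 0.05, 0.6),
                                  R2_slope = runif(1, 0, 0.004),
                                  R3 = runif(1, 0.1, 0.9))
    p <- component_pressures(pressure_state(s, d), cf)
    expect_true(all(p >= d - 1e-9 & p <= s + 1e-9))
    # reflected-pulse pressures strictly between the bounds
    expect_true(all(p[c("P22", "P23", "P32", "P33", "P34", "P35")] > d))
    expect_true(all(p[c("P22", "P23", "P32", "P33", "P34", "P35")] < s))
  }
})

test_that("constant-velocity arrival times equal hand arithmetic to 1e-12", {
  segs <- const_speed_segments(x1 = 0.8, x2 = 0.35, x3 = 0.25)
  at <- arrival_times(pressure_state(120, 80), segs)
  # oracle: path-length sums over 5 m/s
  expect_equal(at$t1, 0.8 / 5, tolerance = 1e-12)
  expect_equal(at$t2, (0.35 + 0.35 + 0.8) / 5, tolerance = 1e-12)
  expect_equal(at$t3, (0.35 + 0.25 + 0.25 + 0.35 + 0.8) / 5, tolerance = 1e-12)
  expect_equal(at$T13, 240, tolerance = 1e-9)
  expect_equal(at$T12, 140, tolerance = 1e-9)
})

test_that("default-calibration delays fall in the physiological windows", {
  at <- arrival_times(pressure_state(120, 80))
  expect_true(at$t1 < at$t2 && at$t2 < at$t3)
  expect_gte(at$T12, 70)
  expect_lte(at$T12, 140)
  expect_gte(at$T13, 180)
  expect_lte(at$T13, 400)
})

test_that("T13-diastole curve: monotone by default, flat when zeta = 0", {
  curve <- t13_pressure_curve(c(70, 80, 90), systole = 120)
  expect_true(all(diff(curve$T13_ms) < 0))   # shortens as diastole rises

  flat <- t13_pressure_curve(c(70, 80, 90), systole = 120,
                             segments = const_speed_segments())
  expect_lt(diff(range(flat$T13_ms)), 1e-9)

  # adjacent systole lines: vertical offset, same slope sign
  c120 <- t13_pressure_curve(seq(60, 100, 5), systole = 120)
  c125 <- t13_pressure_curve(seq(60, 100, 5), systole = 125)
  expect_true(all(sign(diff(c120$T13_ms)) == sign(diff(c125$T13_ms))))
  expect_true(all(c125$T13_ms != c120$T13_ms))

  expect_error(t13_pressure_curve(c(115), systole = 120), "grid")
})

test_that("conservation: zero-PP limit reproduces constant-velocity time", {
  segs <- const_speed_segments()
  at <- arrival_times(pressure_state(100 + 1e-9, 100), segs)
  expect_equal(at$t3 - at$t1, (0.35 + 0.25 + 0.25 + 0.35) / 5,
               tolerance = 1e-9)
})
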