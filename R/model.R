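# Forward pulse-decomposition model.
#
# The peripheral (radial/digital) pressure pulse is modelled as the
# superposition of the primary left-ventricular ejection pulse (#1) and
# reflections from two central sites: the thoracic/abdominal aortic junction
# near the renal arteries (#2, the "renal reflection") and the junction of
# abdominal aorta and common iliac arteries (#3, the "iliac reflection").
# Each component traverses its arterial path legs at a pressure-dependent
# Moens-Korteweg wave speed, so the model predicts the arrival delays T12
# and T13 as functions of the systolic/diastolic pressure state.

#' Arterial segment description
#'
#' Geometry and elasticity of one lumped arterial path of the three-path
#' pulse propagation model: `arm_x1` (aortic arch to the radial/digital
#' measurement site), `thoracic_x2` (aortic valve to the renal reflection
#' site) and `abdominal_x3` (renal site to the iliac reflection site).
#'
#' Wave speed follows the Moens-Korteweg relation
#' \eqn{\nu(P) = \sqrt{h E e^{\zeta P} / (2 \rho \alpha)}} with pressures in
#' mmHg.  `response = "linear"` replaces the exponential pressure response by
#' its first-order expansion about `ref_pressure`; the default calibration
#' uses an exponential response for the muscular arm arteries and linear
#' responses for the central (elastic) aortic segments, which is the
#' combination required to reproduce the observed sign and magnitude of the
#' T13 response to diastolic pressure in the 60--100 mmHg regime.
#'
#' @param name one of `"arm_x1"`, `"thoracic_x2"`, `"abdominal_x3"`.
#' @param length path length in meters.
#' @param wall_thickness arterial wall thickness h in meters.
#' @param youngs_modulus Young's modulus E in pascals.
#' @param diameter vessel diameter alpha in meters.
#' @param fluid_density blood density rho in kg/m^3.
#' @param compliance_exponent pressure sensitivity zeta in 1/mmHg (>= 0).
#' @param response `"exponential"` or `"linear"` pressure-velocity response.
#' @param ref_pressure anchor pressure (mmHg) for the linear expansion.
#' @return an object of class `arterial_segment`.
#' @seealso [default_segments()], [wave_speed()]
#' @export
arterial_segment <- function(name, length, wall_thickness, youngs_modulus,
                             diameter, fluid_density = 1050,
                             compliance_exponent = 0,
                             response = c("exponential", "linear"),
                             ref_pressure = 90) {
  name <- match.arg(name, c("arm_x1", "thoracic_x2", "abdominal_x3"))
  response <- match.arg(response)
  check_scalar(length, "length", 0, strict_lower = TRUE)
  check_scalar(wall_thickness, "wall_thickness", 0, strict_lower = TRUE)
  check_scalar(youngs_modulus, "youngs_modulus", 0, strict_lower = TRUE)
  check_scalar(diameter, "diameter", 0, strict_lower = TRUE)
  check_scalar(fluid_density, "fluid_density", 0, strict_lower = TRUE)
  check_scalar(compliance_exponent, "compliance_exponent", 0)
  check_scalar(ref_pressure, "ref_pressure", 20, 250)
  structure(list(name = name, length = length,
                 wall_thickness = wall_thickness,
                 youngs_modulus = youngs_modulus, diameter = diameter,
                 fluid_density = fluid_density,
                 compliance_exponent = compliance_exponent,
                 response = response, ref_pressure = ref_pressure),
            class = "arterial_segment")
}

#' @export
print.arterial_segment <- function(x, ...) {
  cat(sprintf("<arterial_segment %s: %.2f m, %s response, v(90 mmHg) = %.2f m/s>\n",
              x$name, x$length, x$response, wave_speed(x, 90)))
  invisible(x)
}

#' Default arterial segments
#'
#' Effective path parameters for the cohort the model targets (young adults,
#' mean height about 1.69 m).  Lengths are effective lumped-path lengths and
#' the elasticity values are calibrated so that (i) the thoracic aorta is the
#' slowest segment with a speed of 4--5 m/s at low pressure, (ii) peripheral
#' speeds stay in the physiological 4--9 m/s band, and (iii) the predicted
#' renal and iliac delays at 120/80 mmHg fall inside the observed 70--140 ms
#' and 180--400 ms windows.  All values are plain list entries and can be
#' overridden via [arterial_segment()].
#'
#' @return named list with elements `arm_x1`, `thoracic_x2`, `abdominal_x3`.
#' @export
default_segments <- function() {
  list(
    arm_x1 = arterial_segment("arm_x1", length = 0.80,
                              wall_thickness = 4.0e-4,
                              youngs_modulus = 2.1e5, diameter = 4.0e-3,
                              compliance_exponent = 0.018,
                              response = "exponential"),
    thoracic_x2 = arterial_segment("thoracic_x2", length = 0.26,
                                   wall_thickness = 1.2e-3,
                                   youngs_modulus = 5.1e5, diameter = 0.024,
                                   compliance_exponent = 0.008,
                                   response = "linear"),
    abdominal_x3 = arterial_segment("abdominal_x3", length = 0.28,
                                    wall_thickness = 1.0e-3,
                                    youngs_modulus = 9.1e5, diameter = 0.016,
                                    compliance_exponent = 0.005,
                                    response = "linear")
  )
}

#' Reflection coefficients of the two central reflection sites
#'
#' `R2`, the renal coefficient, is pressure dependent: it is evaluated as an
#' affine function of systolic pressure, clamped to (0, 1), anchored at
#' `R2_at_ref` for `ref_systole` (default 0.17 at 120 mmHg, i.e. a renal
#' reflection of about 17%).  `R3` is the iliac coefficient (default 0.40:
#' the iliac reflection carries about 40% of pulse pressure).  `R1` is the
#' transmission loss at the aortic/subclavian junction on entry into the arm
#' complex.
#'
#' @param R1 arm-entry/junction coefficient in \[0, 1).
#' @param R2_at_ref renal coefficient at the reference systole, in (0, 1).
#' @param R2_slope pressure sensitivity of the renal coefficient (1/mmHg).
#' @param R3 iliac coefficient in (0, 1).
#' @param ref_systole reference systolic pressure (mmHg).
#' @return an object of class `reflection_coefficients`.
#' @export
reflection_coefficients <- function(R1 = 0.10, R2_at_ref = 0.17,
                                    R2_slope = 0.002, R3 = 0.40,
                                    ref_systole = 120) {
  check_scalar(R1, "R1", 0, 1, strict_upper = TRUE)
  check_scalar(R2_at_ref, "R2_at_ref", 0, 1, TRUE, TRUE)
  check_scalar(R2_slope, "R2_slope")
  check_scalar(R3, "R3", 0, 1, TRUE, TRUE)
  check_scalar(ref_systole, "ref_systole", 60, 250)
  structure(list(R1 = R1, R2_at_ref = R2_at_ref, R2_slope = R2_slope,
                 R3 = R3, ref_systole = ref_systole),
            class = "reflection_coefficients")
}

#' Pressure state
#'
#' @param systolic systolic pressure (mmHg).
#' @param diastolic diastolic pressure (mmHg); must satisfy
#'   `systolic > diastolic > 0`.
#' @return object of class `pressure_state` with fields `Psyst`, `Pdiast`
#'   and the derived `PPulse = Psyst - Pdiast`.
#' @export
pressure_state <- function(systolic, diastolic) {
  check_scalar(systolic, "systolic", 0, strict_lower = TRUE)
  check_scalar(diastolic, "diastolic", 0, strict_lower = TRUE)
  if (systolic <= diastolic)
    stop_invalid("systolic must exceed diastolic (got ", systolic, "/",
                 diastolic, ")")
  structure(list(Psyst = systolic, Pdiast = diastolic,
                 PPulse = systolic - diastolic), class = "pressure_state")
}

#' Pressure-dependent arterial wave speed
#'
#' Moens-Korteweg wave speed of a segment at pressure `pressure`.  For
#' exponential segments this is
#' \eqn{\sqrt{h E e^{\zeta P} / (2 \rho \alpha)}}; linear segments use the
#' first-order expansion of that expression about the segment's
#' `ref_pressure`, i.e.
#' \eqn{\nu(P_0) (1 + \tfrac{\zeta}{2}(P - P_0))}.
#'
#' @param segment an [arterial_segment()].
#' @param pressure pressure(s) in mmHg, each in \[20, 250\].
#' @return wave speed(s) in m/s.
#' @examples
#' seg <- arterial_segment("arm_x1", 0.8, 0.001, 4e5, 0.01)
#' wave_speed(seg, 100)  # 4.36 m/s, pressure-independent since zeta = 0
#' @export
wave_speed <- function(segment, pressure) {
  if (!inherits(segment, "arterial_segment"))
    stop_invalid("segment must be an arterial_segment")
  if (!is.numeric(pressure) || any(!is.finite(pressure)))
    stop_invalid("pressure must be finite numeric")
  if (any(pressure < 20 | pressure > 250))
    stop_invalid("pressure outside the supported range [20, 250] mmHg")
  base <- segment$wall_thickness * segment$youngs_modulus /
    (2 * segment$fluid_density * segment$diameter)
  z <- segment$compliance_exponent
  if (segment$response == "exponential") {
    v <- sqrt(base * exp(z * pressure))
  } else {
    v0 <- sqrt(base * exp(z * segment$ref_pressure))
    v <- v0 * (1 + z / 2 * (pressure - segment$ref_pressure))
  }
  if (any(v <= 0))
    stop_invalid("non-positive wave speed; linear response leaves its ",
                 "validity range for segment ", segment$name)
  v
}

#' Renal reflection coefficient at a given systolic pressure
#'
#' The renal site sits at a step change in aortic diameter; rising systole
#' widens the mismatch between the compliant thoracic and the stiffer
#' abdominal aorta, so the coefficient grows with systolic pressure.  The
#' functional form is affine with clamping:
#' `R2 = clamp(R2_at_ref + R2_slope * (Psyst - ref_systole), eps, 1 - eps)`.
#'
#' @param Psyst systolic pressure in mmHg, in \[60, 250\].
#' @param coeffs a [reflection_coefficients()] object.
#' @param eps clamp margin keeping the result strictly inside (0, 1).
#' @return dimensionless coefficient in (0, 1).
#' @export
renal_reflection_coefficient <- function(Psyst, coeffs = reflection_coefficients(),
                                         eps = 1e-6) {
  if (!is.numeric(Psyst) || any(Psyst < 60 | Psyst > 250))
    stop_invalid("Psyst must lie in [60, 250] mmHg")
  r <- coeffs$R2_at_ref + coeffs$R2_slope * (Psyst - coeffs$ref_systole)
  pmin(pmax(r, eps), 1 - eps)
}

#' Component-pulse pressures
#'
#' Pressures at which each leg of each analyzed component pulse loads the
#' arterial wall.  The primary pulse travels at systolic pressure; after a
#' reflection with coefficient R a pulse carries diastole plus R times pulse
#' pressure, with further factors (1 - R) for transmission through a site it
#' crosses.  Indices P<n><m> follow the path-leg bookkeeping of the arrival
#' time equations: n is the component pulse, m the leg.
#'
#' @param state a [pressure_state()].
#' @param coeffs a [reflection_coefficients()]; R2 is evaluated at
#'   `state$Psyst` via [renal_reflection_coefficient()].
#' @return object of class `component_pressures`: named numeric vector with
#'   entries P11, P21, P22, P23, P31, P32, P33, P34, P35 (mmHg).
#' @export
component_pressures <- function(state, coeffs = reflection_coefficients()) {
  if (!inherits(state, "pressure_state"))
    stop_invalid("state must be a pressure_state")
  R1 <- coeffs$R1
  R2 <- renal_reflection_coefficient(state$Psyst, coeffs)
  R3 <- coeffs$R3
  PP <- state$PPulse
  Pd <- state$Pdiast
  Ps <- state$Psyst
  p <- c(P11 = Ps - R1 * PP,
         P21 = Ps,
         P22 = Pd + R2 * PP,
         P23 = Pd + R2 * (1 - R1) * PP,
         P31 = Ps,
         P32 = Ps - R2 * PP,
         P33 = Pd + R3 * (1 - R2) * PP,
         P34 = Pd + R3 * (1 - R2) * (1 - R2) * PP,
         P35 = Pd + R3 * (1 - R2) * (1 - R2) * (1 - R1) * PP)
  tol <- 1e-9 * max(1, Ps)
  bad <- names(p)[p < Pd - tol | p > Ps + tol]
  if (length(bad))
    stop_invalid("model inconsistency: component pressure(s) ",
                 paste(bad, collapse = ", "), " outside [diastole, systole]")
  structure(p, class = "component_pressures", R2 = unname(R2))
}

#' Component-pulse arrival times
#'
#' Arrival times at the peripheral measurement site of the primary pulse
#' (t1), the renal reflection (t2) and the iliac reflection (t3), as sums of
#' path-leg travel times at the leg's component pressure:
#' \deqn{t_1 = x_1/\nu_{x1}(P_{11})}
#' \deqn{t_2 = x_2/\nu_{x2}(P_{21}) + x_2/\nu_{x2}(P_{22}) + x_1/\nu_{x1}(P_{23})}
#' \deqn{t_3 = x_2/\nu_{x2}(P_{31}) + x_3/\nu_{x3}(P_{32}) + x_3/\nu_{x3}(P_{33})
#'       + x_2/\nu_{x2}(P_{34}) + x_1/\nu_{x1}(P_{35})}
#' The final leg of every component runs through the arm segment with the
#' arm's velocity function.
#'
#' @param state a [pressure_state()].
#' @param segments named list with `arm_x1`, `thoracic_x2`, `abdominal_x3`
#'   entries (see [default_segments()]).
#' @param coeffs a [reflection_coefficients()].
#' @return object of class `arrival_times`: list with `t1`, `t2`, `t3` in
#'   seconds and the delays `T12`, `T13` in milliseconds.
#' @examples
#' at <- arrival_times(pressure_state(120, 80))
#' c(at$T12, at$T13)  # renal and iliac delays in ms
#' @export
arrival_times <- function(state, segments = default_segments(),
                          coeffs = reflection_coefficients()) {
  need <- c("arm_x1", "thoracic_x2", "abdominal_x3")
  if (!all(need %in% names(segments)))
    stop_invalid("segments must contain ", paste(need, collapse = ", "))
  p <- component_pressures(state, coeffs)
  arm <- segments$arm_x1; tho <- segments$thoracic_x2; abd <- segments$abdominal_x3
  x1 <- arm$length; x2 <- tho$length; x3 <- abd$length
  t1 <- x1 / wave_speed(arm, p[["P11"]])
  t2 <- x2 / wave_speed(tho, p[["P21"]]) +
        x2 / wave_speed(tho, p[["P22"]]) +
        x1 / wave_speed(arm, p[["P23"]])
  t3 <- x2 / wave_speed(tho, p[["P31"]]) +
        x3 / wave_speed(abd, p[["P32"]]) +
        x3 / wave_speed(abd, p[["P33"]]) +
        x2 / wave_speed(tho, p[["P34"]]) +
        x1 / wave_speed(arm, p[["P35"]])
  if (!(t1 < t2 && t2 < t3))
    stop_invalid("model inconsistency: arrival times not ordered t1 < t2 < t3")
  structure(list(t1 = t1, t2 = t2, t3 = t3,
                 T12 = (t2 - t1) * 1000, T13 = (t3 - t1) * 1000,
                 pressures = p),
            class = "arrival_times")
}

#' @export
print.arrival_times <- function(x, ...) {
  cat(sprintf("<arrival_times t1=%.1f ms t2=%.1f ms t3=%.1f ms | T12=%.1f ms T13=%.1f ms>\n",
              x$t1 * 1000, x$t2 * 1000, x$t3 * 1000, x$T12, x$T13))
  invisible(x)
}

#' T13 versus diastolic pressure curve
#'
#' Evaluates the forward model on a grid of diastolic pressures at fixed
#' systole, producing one member of the curve family that summarizes how the
#' iliac delay responds to pulse-pressure changes driven entirely by
#' diastole.  Under the default calibration (exponential arm response,
#' linear central response) T13 shortens as diastole rises toward systole.
#'
#' @param diastole_grid diastolic pressures in mmHg; each must lie in
#'   \[40, systole - 10\].
#' @param systole fixed systolic pressure (mmHg).
#' @param segments,coeffs forward-model parameters.
#' @return data.frame with columns `diastole_mmHg`, `T12_ms`, `T13_ms`.
#' @export
t13_pressure_curve <- function(diastole_grid, systole = 120,
                               segments = default_segments(),
                               coeffs = reflection_coefficients()) {
  check_scalar(systole, "systole", 60, 250)
  if (!is.numeric(diastole_grid) || length(diastole_grid) == 0)
    stop_invalid("diastole_grid must be a non-empty numeric vector")
  if (any(diastole_grid < 40 | diastole_grid > systole - 10))
    stop_invalid("diastole_grid must lie within [40, systole - 10] mmHg")
  rows <- lapply(diastole_grid, function(d) {
    at <- arrival_times(pressure_state(systole, d), segments, coeffs)
    data.frame(diastole_mmHg = d, T12_ms = at$T12, T13_ms = at$T13)
  })
  do.call(rbind, rows)
}
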