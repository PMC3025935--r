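# Run configuration: schema, defaults, JSON round-trip and hashing.
#
# One nested configuration drives the whole pipeline.  Unknown keys are
# rejected (typos should fail loudly), missing keys fall back to the
# documented defaults, and a short content hash of the canonical JSON form
# is embedded in every pipeline output for provenance.

segment_to_list <- function(seg) {
  seg[c("name", "length", "wall_thickness", "youngs_modulus", "diameter",
        "fluid_density", "compliance_exponent", "response", "ref_pressure")]
}

#' Default run configuration
#'
#' @return nested list with blocks `model`, `synth`, `extract`, `stats`,
#'   plus `seed` and `log_level`.  All values equal the documented
#'   per-function defaults.
#' @export
default_config <- function() {
  segs <- default_segments()
  opts <- extract_opts()
  list(
    model = list(
      segments = lapply(segs, segment_to_list),
      reflection_coefficients = unclass(reflection_coefficients()),
      pressure_state = list(systolic = 120, diastolic = 80)
    ),
    synth = list(
      stages = default_lbnp_stages(),
      sample_rate = 512,
      noise_sd = 0.02,
      base_hr = 65,
      hr_jitter_sd = 1,
      amplitudes = c(1.0, 0.30, 0.40, 0.08, 0.02),
      width = 60,
      skew = 0.3
    ),
    extract = unclass(opts),
    stats = list(alpha = 0.01, anova_stages = c(0, -15, -30),
                 anova_mode = "joint",
                 roc = list(stage_a = -15, stage_b = -30, baseline = 0)),
    seed = 1,
    log_level = "info"
  )
}

## Recursive merge of user values into defaults; unknown keys error.
merge_config <- function(user, defaults, path = "") {
  if (!is.list(user) || !is.list(defaults) || is.data.frame(defaults))
    return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_invalid("unknown configuration key(s): ",
                 paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                        collapse = ", "))
  for (k in names(user))
    defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                  paste0(path, ".", k))
  defaults
}

#' Load / save a run configuration
#'
#' `load_config()` reads a JSON configuration, validates it against the
#' schema (unknown keys are an error, naming the offending key) and fills
#' unspecified values with the defaults.  `save_config()` writes the
#' canonical JSON form; a default configuration round-trips
#' load -> save -> load identically.
#'
#' @param path JSON file path.
#' @return the validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(user, default_config())
  cfg$synth$stages <- as.data.frame(cfg$synth$stages)
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config configuration list.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

validate_config <- function(config) {
  cfg_segments(config)
  cfg_coeffs(config)
  cfg_state(config)
  cfg_opts(config)
  if (!config$log_level %in% c("debug", "info", "warning", "error"))
    stop_invalid("log_level must be one of debug/info/warning/error")
  invisible(config)
}

#' Configuration content hash
#'
#' Deterministic 8-hex-digit hash of the canonical JSON serialization,
#' stamped into all pipeline outputs.
#'
#' @param config configuration list.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  content_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"))
}

## Constructors from a configuration block.
cfg_segments <- function(config) {
  lapply(config$model$segments, function(s)
    arterial_segment(s$name, s$length, s$wall_thickness, s$youngs_modulus,
                     s$diameter, s$fluid_density, s$compliance_exponent,
                     s$response, s$ref_pressure))
}

cfg_coeffs <- function(config) {
  r <- config$model$reflection_coefficients
  reflection_coefficients(r$R1, r$R2_at_ref, r$R2_slope, r$R3, r$ref_systole)
}

cfg_state <- function(config) {
  p <- config$model$pressure_state
  pressure_state(p$systolic, p$diastolic)
}

cfg_opts <- function(config) {
  e <- config$extract
  extract_opts(e$p2_window, e$p3_window, e$integrator_hz, e$baseline_hz,
               e$primary_hz, e$refractory_ms, e$min_beat_ms,
               e$snr_threshold_db, e$snr_band, e$snr_ceiling_db, e$peak_frac)
}

cfg_session_spec <- function(config, seed = NULL) {
  s <- config$synth
  session_spec(stages = as.data.frame(s$stages), sample_rate = s$sample_rate,
               noise_sd = s$noise_sd, seed = seed %||% config$seed,
               base_state = cfg_state(config), base_hr = s$base_hr,
               hr_jitter_sd = s$hr_jitter_sd, amplitudes = s$amplitudes,
               width = s$width, skew = s$skew)
}

pda_log <- function(config, level, ...) {
  levels <- c(debug = 1, info = 2, warning = 3, error = 4)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, paste0(...)))
}
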