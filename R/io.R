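# Plain-text readers and writers for streams, ground truth and beat tables.
#
# Stream files are two-column delimited text (sample_index, derivative)
# with a JSON sidecar holding the sampling rate, seed and stage schedule,
# so a stream round-trips without loss of provenance.

#' Write / read a derivative stream
#'
#' @param session a `synth_session` or [derivative_stream()].
#' @param path output CSV path; the JSON sidecar is written to
#'   `<path>.json`.
#' @param digits significant digits for the sample values.
#' @return `path`, invisibly.
#' @export
write_stream <- function(session, path, digits = 10) {
  stream <- if (inherits(session, "synth_session")) session$stream else session
  if (!inherits(stream, "derivative_stream"))
    stop_invalid("session must be a synth_session or derivative_stream")
  df <- data.frame(sample_index = seq_along(stream$samples) - 1L,
                   derivative = signif(stream$samples, digits))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(sample_rate = stream$sample_rate)
  if (inherits(session, "synth_session")) {
    sidecar$seed <- session$spec$seed
    sidecar$noise_sd <- session$spec$noise_sd
    sidecar$stages <- session$spec$stages
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stream
#' @param sample_rate sampling rate to assume when no sidecar is present.
#' @export
read_stream <- function(path, sample_rate = 512) {
  df <- utils::read.csv(path)
  if (!"derivative" %in% names(df))
    stop_invalid("stream file must have a 'derivative' column")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    sample_rate <- meta$sample_rate %||% sample_rate
  }
  derivative_stream(df$derivative, sample_rate)
}

#' Write / read a ground-truth table
#' @param truth truth data.frame (see [synthesize_session()]).
#' @param path CSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) utils::read.csv(path)

#' Write / read an extracted beat table
#' @param extraction a `pda_extraction` (or plain beats data.frame).
#' @param path CSV path; the quality report goes to `qc_path` when given.
#' @param qc_path optional JSON path for the quality report.
#' @export
write_beats <- function(extraction, path, qc_path = NULL) {
  beats <- if (inherits(extraction, "pda_extraction")) extraction$beats
           else extraction
  utils::write.csv(beats, path, row.names = FALSE)
  if (!is.null(qc_path) && inherits(extraction, "pda_extraction"))
    jsonlite::write_json(extraction$quality, qc_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) utils::read.csv(path)
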