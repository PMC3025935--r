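# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("pulsedecomp_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (strict_lower && x <= lower) stop_invalid(name, " must be > ", lower)
  if (!strict_lower && x < lower) stop_invalid(name, " must be >= ", lower)
  if (strict_upper && x >= upper) stop_invalid(name, " must be < ", upper)
  if (!strict_upper && x > upper) stop_invalid(name, " must be <= ", upper)
  invisible(x)
}

## Evaluate `expr` with the global RNG seeded at `seed`, restoring the caller's
## RNG state afterwards.  All stochastic stages funnel through this so that a
## single session/config seed gives bit-reproducible output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of sub-seeds from one master seed (kept below 2^31).
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1103 * as.numeric(k)) %% 2147483647
}

## Sub-sample refinement of an extremum at index i of y by fitting a parabola
## through (i-1, i, i+1).  Returns fractional offset in [-0.5, 0.5] plus the
## interpolated extremal value.
parabolic_refine <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(list(offset = 0, value = y[i]))
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(list(offset = 0, value = y[i]))
  off <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  off <- max(-0.5, min(0.5, off))
  list(offset = off, value = y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * off)
}

## Linear interpolation of y at fractional 1-based index.
interp_at <- function(y, idx) {
  i <- floor(idx)
  f <- idx - i
  i <- max(1L, min(length(y) - 1L, as.integer(i)))
  y[i] * (1 - f) + y[i + 1L] * f
}

## Deterministic 32-bit polynomial hash of a character scalar, as 8 hex
## digits.  Used to stamp pipeline outputs with the configuration they were
## produced from (provenance, not cryptography).
content_hash <- function(x) {
  bytes <- as.numeric(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) h <- ((h + b) * 16777619) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
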