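# IIR filter design and application.
#
# The extractor needs three small filters: a Bessel low-pass behind the
# digital integrator, a Butterworth low-pass for primary-peak identification,
# and a first-order high-pass for baseline removal.  They are designed from
# the analog prototypes by bilinear transform with frequency pre-warping;
# coefficients agree with scipy.signal to ~1e-12 (checked in the test suite
# against frozen reference values).

## Coefficients of the reverse Bessel polynomial theta_n(s) in ascending
## powers of s (constant term first).
bessel_reverse_poly <- function(n) {
  k <- 0:n
  factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
}

## Analog prototype (poles, gain) of an n-th order Bessel low-pass,
## magnitude-normalized so that |H(jw)| = 1/sqrt(2) at w = 1.
bessel_prototype <- function(n) {
  co <- bessel_reverse_poly(n)    # ascending powers
  p <- polyroot(co)
  k0 <- co[1]                     # H(s) = k0 / theta_n(s), so H(0) = 1
  gain2 <- function(w) {
    s <- complex(real = 0, imaginary = w)
    (k0 / Mod(sum(co * s^(0:n))))^2
  }
  wc <- stats::uniroot(function(w) gain2(w) - 0.5, c(1e-4, 10), tol = 1e-14)$root
  list(poles = p / wc, gain = k0 / wc^n)
}

## Analog prototype of an n-th order Butterworth low-pass (-3 dB at w = 1).
butter_prototype <- function(n) {
  k <- seq_len(n)
  list(poles = exp(1i * pi * (2 * k + n - 1) / (2 * n)), gain = 1)
}

poly_from_roots <- function(r) {
  co <- 1 + 0i
  for (ri in r) co <- c(co, 0) - c(0, co * ri)
  co
}

## Bilinear transform of an all-pole analog low-pass prototype to digital
## (b, a) at cutoff fc (Hz) and sampling rate fs (Hz).
design_lowpass <- function(prototype, fc, fs) {
  wa <- 2 * fs * tan(pi * fc / fs)
  p <- prototype$poles * wa
  k <- prototype$gain * wa^length(p)
  fs2 <- 2 * fs
  pd <- (fs2 + p) / (fs2 - p)
  kd <- Re(k / prod(fs2 - p))
  b <- kd * Re(poly_from_roots(rep(-1, length(p))))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

bessel_lowpass <- function(fc, fs, order = 4L) {
  check_scalar(fc, "fc", 0, fs / 2, TRUE, TRUE)
  design_lowpass(bessel_prototype(order), fc, fs)
}

butter_lowpass <- function(fc, fs, order = 2L) {
  check_scalar(fc, "fc", 0, fs / 2, TRUE, TRUE)
  design_lowpass(butter_prototype(order), fc, fs)
}

## First-order Butterworth high-pass: H(s) = s / (s + wa).
butter_highpass1 <- function(fc, fs) {
  check_scalar(fc, "fc", 0, fs / 2, TRUE, TRUE)
  wa <- 2 * fs * tan(pi * fc / fs)
  fs2 <- 2 * fs
  b0 <- fs2 / (fs2 + wa)
  list(b = c(b0, -b0), a = c(1, -(fs2 - wa) / (fs2 + wa)))
}

## Direct-form IIR filtering with zero initial conditions.  The MA part is a
## one-sided convolution and the AR part a linear recursion; both run in C
## through stats::filter.
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  if (nb > 1L) {
    xp <- c(rep(0, nb - 1L), x)
    v <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
    v <- v[nb:length(xp)]
  } else {
    v <- b * x
  }
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  v
}

## Zero-phase (forward-backward) filtering with odd-reflection edge padding.
## `npad` controls the padding length; slow filters (the 0.3 Hz baseline
## high-pass) need padding of the order of their settling time.
filtfilt0 <- function(b, a, x, npad = NULL) {
  n <- length(x)
  if (n < 4L) return(x)
  npad <- min(n - 1L, as.integer(npad %||% (3L * (max(length(a), length(b)) - 1L) + 32L)))
  front <- 2 * x[1] - x[(npad + 1L):2]
  back <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- iir_filter(b, a, c(front, x, back))
  y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1L):(npad + n)]
}
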