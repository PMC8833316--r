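# Internal frequency-domain signal engine shared by the preprocessing,
# beamformer and PAC modules.  All zero-phase filtering in the package is
# Butterworth |H(w)|^2 applied to the FFT of each series, i.e. the
# steady-state response of a bidirectionally applied IIR filter; boundary
# (wrap-around) transients are absorbed by the epoch padding, which every
# windowed statistic trims before averaging.

#' Design a digital Butterworth filter and check stability
#'
#' Thin wrapper around [signal::butter()] that validates corner placement
#' against the Nyquist frequency and rejects unstable designs.
#'
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Band edges in Hz (`low_hz` may be `NULL` for a
#'   low-pass, `high_hz` `NULL` for a high-pass).
#' @param order Filter order (per pass; applied bidirectionally downstream).
#' @param type `"pass"` or `"stop"`.
#' @return An `Arma` coefficient object from the signal package.
#' @keywords internal
design_butter <- function(fs, low_hz, high_hz, order = 4, type = "pass") {
  nyq <- fs / 2
  if (!is.null(high_hz) && high_hz >= nyq * 0.999)
    stop("filter corner ", high_hz, " Hz too close to Nyquist (", nyq, " Hz)")
  if (!is.null(low_hz) && low_hz <= 0)
    stop("filter corner must be > 0 Hz")
  w <- if (is.null(low_hz)) {
    signal::butter(order, high_hz / nyq, type = "low")
  } else if (is.null(high_hz)) {
    signal::butter(order, low_hz / nyq, type = "high")
  } else {
    if (low_hz >= high_hz) stop("low_hz must be < high_hz")
    signal::butter(order, c(low_hz, high_hz) / nyq, type = type)
  }
  if (any(abs(polyroot(rev(w$a))) > 1 + 1e-8))
    stop("unstable Butterworth design (corner too close to Nyquist); ",
         "reduce the order or move the band edge")
  w
}

# |H(e^{-iw})|^2 of an ARMA filter at the n FFT bin frequencies.
butter_gain2 <- function(coef, n) {
  w <- 2 * pi * (seq_len(n) - 1) / n
  z <- exp(-1i * w)
  h <- outer(z, seq_along(coef$b) - 1, `^`) %*% coef$b /
       (outer(z, seq_along(coef$a) - 1, `^`) %*% coef$a)
  as.numeric(Mod(h)^2)
}

# Apply a real zero-phase gain (length n vector) to a vector or the columns
# of a matrix; returns the same shape.
apply_gain <- function(x, gain) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  stopifnot(nrow(X) == length(gain))
  Y <- Re(stats::mvfft(stats::mvfft(X) * gain, inverse = TRUE)) / nrow(X)
  if (vec) drop(Y) else Y
}

# Analytic (Hilbert) band signal: zero-phase band-pass gain plus one-sided
# spectrum doubling.  Returns complex, same shape as x.
analytic_band <- function(x, gain) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  stopifnot(n == length(gain))
  mask <- numeric(n)
  half <- floor(n / 2)
  mask[1] <- 1
  if (n %% 2 == 0) {
    mask[half + 1] <- 1
    if (half > 1) mask[2:half] <- 2
  } else if (half >= 1) {
    mask[2:(half + 1)] <- 2
  }
  Y <- stats::mvfft(stats::mvfft(X) * (gain * mask), inverse = TRUE) / n
  if (vec) drop(Y) else Y
}

# Seed derivation for reproducible nested simulation streams; keeps the
# derived seed inside 32-bit integer range.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(i)) %% 2147483629L)
}
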