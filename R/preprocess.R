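#' Band-pass / band-stop filter specification
#'
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param low_hz,high_hz Band edges (Hz), `0 < low < high < fs/2`.
#' @param order Butterworth order (default 4), applied bidirectionally.
#' @param bidirectional Zero-phase application (the only mode implemented;
#'   kept as an explicit, asserted field).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "bandstop"), low_hz, high_hz,
                        order = 4, bidirectional = TRUE) {
  kind <- match.arg(kind)
  stopifnot(low_hz > 0, low_hz < high_hz, order >= 1, isTRUE(bidirectional))
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 order = order, bidirectional = TRUE), class = "filter_spec")
}

#' Zero-phase Butterworth filtering
#'
#' Applies a bidirectional (zero-phase) Butterworth band-pass or band-stop
#' filter.  The filter is designed with [signal::butter()] and its squared
#' magnitude response is applied in the frequency domain, which is the
#' steady-state equivalent of forward-backward (filtfilt) application;
#' wrap-around transients are confined to the epoch padding.
#'
#' @param x Numeric vector, or matrix with series in columns.
#' @param fs Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered data, same shape and length as `x`.
#' @export
butter_filter <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_hz >= fs / 2)
    stop("high corner ", spec$high_hz, " Hz not below Nyquist (", fs / 2, " Hz)")
  coef <- design_butter(fs, spec$low_hz, spec$high_hz, spec$order,
                        type = if (spec$kind == "bandpass") "pass" else "stop")
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  apply_gain(x, butter_gain2(coef, n))
}

#' Power-line notch filtering at a base frequency and its harmonics
#'
#' Sequential zero-phase band-stop filters at `base_hz, 2*base_hz, ...,
#' n_harmonics*base_hz`, each of width `±half_width_hz`.
#'
#' @param x Vector or matrix (series in columns).
#' @param fs Sampling rate (Hz).
#' @param base_hz Line frequency (default 50 Hz).
#' @param n_harmonics Number of harmonics to remove, all below Nyquist.
#' @param half_width_hz Half-width of each stop band (default 1 Hz; narrow,
#'   to minimally distort the gamma amplitude band).
#' @param order Butterworth order per stop band.
#' @return Filtered data, same shape as `x`.
#' @export
notch_harmonics <- function(x, fs, base_hz = 50, n_harmonics = 3,
                            half_width_hz = 1, order = 4) {
  stopifnot(n_harmonics >= 1)
  if (n_harmonics * base_hz + half_width_hz >= fs / 2)
    stop("harmonic ", n_harmonics * base_hz, " Hz at or above Nyquist")
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  gain <- rep(1, n)
  for (k in seq_len(n_harmonics)) {
    coef <- design_butter(fs, k * base_hz - half_width_hz,
                          k * base_hz + half_width_hz, order, type = "stop")
    gain <- gain * butter_gain2(coef, n)
  }
  apply_gain(x, gain)
}

#' Epoch a continuous recording around stimulus onsets
#'
#' Cuts `[-(pre_s + pad_s), post_s + pad_s)` second windows around each
#' onset sample.  Onsets whose padded window falls outside the recording
#' are rejected with their indices reported.
#'
#' @param x Continuous data: vector or `channels x samples` matrix.
#' @param fs Sampling rate (Hz).
#' @param onsets Stimulus onset sample indices (1-based).
#' @param pre_s,post_s Analysis window before/after onset (s).
#' @param pad_s Padding on each side (s).
#' @param ... Passed to [epoch_set()] (subject, group, truth).
#' @return An [epoch_set()]; time axis zero at onset.
#' @export
epoch_continuous <- function(x, fs, onsets, pre_s = 1.5, post_s = 1.5,
                             pad_s = 2.5, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  n_pre <- round((pre_s + pad_s) * fs)
  n_post <- round((post_s + pad_s) * fs)
  bad <- which(onsets - n_pre < 1 | onsets + n_post - 1 > n)
  if (length(bad))
    stop("onset(s) too close to the recording edge at index ",
         paste(bad, collapse = ", "), " (sample ",
         paste(onsets[bad], collapse = ", "), ")")
  nt <- length(onsets); nc <- nrow(x)
  dat <- array(0, c(nt, nc, n_pre + n_post))
  for (i in seq_len(nt))
    dat[i, , ] <- x[, (onsets[i] - n_pre):(onsets[i] + n_post - 1), drop = FALSE]
  times <- (seq_len(n_pre + n_post) - n_pre - 1) / fs
  epoch_set(dat, times, fs, pad_s = pad_s, ...)
}

#' Decimate epochs to a lower sampling rate
#'
#' Applies a zero-phase Butterworth anti-alias low-pass (default corner
#' `0.45 * target_fs`) and resamples by Fourier-domain truncation, which is
#' exact for band-limited content; the epoch duration and time-axis
#' endpoints are preserved to within one output sample.
#'
#' @param epochs An [epoch_set()].
#' @param target_fs Target sampling rate (Hz), below the current rate.
#' @param aa_corner_hz Anti-alias corner (Hz); default `0.45 * target_fs`.
#' @param aa_order Anti-alias Butterworth order.
#' @return Decimated [epoch_set()].
#' @export
decimate_epochs <- function(epochs, target_fs = 300, aa_corner_hz = NULL,
                            aa_order = 8) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  if (target_fs >= fs) stop("target_fs must be below the current rate")
  if (is.null(aa_corner_hz)) aa_corner_hz <- 0.45 * target_fs
  n <- n_samples(epochs)
  m <- round(n * target_fs / fs)
  fs_out <- m / (n / fs)                       # exact output rate
  gain <- butter_gain2(design_butter(fs, NULL, aa_corner_hz, aa_order), n)
  nt <- n_trials(epochs); nc <- n_channels(epochs)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)   # samples x (tr*ch)
  X <- stats::mvfft(flat) * gain
  # Rebuild an m-point spectrum from the low-frequency part of X
  Y <- matrix(0 + 0i, m, ncol(X))
  hm <- floor(m / 2)
  Y[1:(hm + 1), ] <- X[1:(hm + 1), , drop = FALSE]
  if (hm >= 1) Y[(m - hm + 1):m, ] <- X[(n - hm + 1):n, , drop = FALSE]
  if (m %% 2 == 0) Y[hm + 1, ] <- Re(Y[hm + 1, ])            # real Nyquist bin
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / n               # includes m/n scale
  dat <- aperm(array(y, c(m, nt, nc)), c(2, 3, 1))
  times <- epochs$times[1] + (seq_len(m) - 1) / fs_out
  epoch_set(dat, times, fs_out, subject = epochs$subject, group = epochs$group,
            pad_s = epochs$pad_s, truth = epochs$truth)
}

#' Standard pre-processing chain for raw epochs
#'
#' Band-pass 0.5-250 Hz (4th-order Butterworth, zero-phase), notch filters
#' at the power-line frequency and harmonics, then decimation to
#' `target_fs`.  Filtering operates on the padded epochs, so edge
#' transients never reach the analysis window.
#'
#' @param epochs Raw [epoch_set()].
#' @param bp Band-pass [filter_spec()].
#' @param line_hz Line frequency for [notch_harmonics()]; `NULL` skips.
#' @param n_harmonics Harmonics to notch.
#' @param target_fs Output sampling rate (Hz); `NULL` skips decimation.
#' @return Pre-processed [epoch_set()].
#' @export
preprocess_epochs <- function(epochs,
                              bp = filter_spec("bandpass", 0.5,
                                               min(250, epochs$fs / 2 - 1)),
                              line_hz = 50, n_harmonics = 3,
                              target_fs = 300) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- n_samples(epochs)
  gain <- butter_gain2(design_butter(epochs$fs, bp$low_hz, bp$high_hz,
                                     bp$order,
                                     if (bp$kind == "bandpass") "pass" else "stop"), n)
  if (!is.null(line_hz))
    for (k in seq_len(n_harmonics))
      gain <- gain * butter_gain2(design_butter(epochs$fs,
                k * line_hz - 1, k * line_hz + 1, 4, "stop"), n)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)
  y <- apply_gain(flat, gain)
  out <- epochs
  out$data <- aperm(array(y, c(n, n_trials(epochs), n_channels(epochs))),
                    c(2, 3, 1))
  if (!is.null(target_fs) && target_fs < epochs$fs)
    out <- decimate_epochs(out, target_fs)
  out
}
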