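.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal
#' commuting matrix, ordered by decreasing energy concentration and
#' normalised to unit energy.
#'
#' @param n Taper length (samples).
#' @param nw Time-bandwidth product (e.g. `0.5 s * 7 Hz = 3.5`).
#' @param k Number of tapers (default `floor(2 * nw - 1)`).
#' @return `n x k` matrix, one taper per column, `colSums(h^2) = 1`.
#' @export
dpss_tapers <- function(n, nw, k = floor(2 * nw - 1)) {
  stopifnot(n >= 2, nw > 0, k >= 1, k < n)
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  W <- nw / n
  t0 <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_v
  A[cbind(1:(n - 1), 2:n)] <- off_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  e <- eigen(A, symmetric = TRUE)
  h <- e$vectors[, seq_len(k), drop = FALSE]
  h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
  for (j in seq_len(k)) if (sum(h[, j]) < 0 ||
      (abs(sum(h[, j])) < 1e-8 && h[which.max(abs(h[, j])), j] < 0))
    h[, j] <- -h[, j]
  .taper_cache[[key]] <- h
  h
}

# Shared sliding-window tapered spectrogram.  tapers: n_win x k matrix with
# unit-energy columns.  Returns trial-averaged two-sided PSD (freq x time).
sliding_tfr <- function(ve, freqs, win_s, step_s, tapers, method) {
  stopifnot(inherits(ve, "epoch_set"), n_channels(ve) == 1L,
            all(diff(freqs) > 0))
  fs <- ve$fs
  n_win <- nrow(tapers)
  X <- t(ve_matrix(ve))                         # samples x trials
  t_lo <- min(ve$times) + ve$pad_s
  t_hi <- max(ve$times) - ve$pad_s
  centers <- seq(t_lo, t_hi, by = step_s)
  half <- (n_win - 1) / 2
  t_rel <- (seq_len(n_win) - 1 - half) / fs
  E <- exp(-2i * pi * outer(freqs, t_rel))      # nf x n_win
  EH <- lapply(seq_len(ncol(tapers)),
               function(k) E * rep(tapers[, k], each = length(freqs)))
  P <- matrix(0, length(freqs), length(centers))
  for (ci in seq_along(centers)) {
    i0 <- which.min(abs(ve$times - centers[ci])) - floor(half)
    if (i0 < 1 || i0 + n_win - 1 > nrow(X))
      stop("window at t=", centers[ci], " s does not fit in the padded epoch")
    seg <- X[i0:(i0 + n_win - 1), , drop = FALSE]
    acc <- 0
    for (k in seq_along(EH)) acc <- acc + Mod(EH[[k]] %*% seg)^2
    P[, ci] <- rowMeans(acc) / (length(EH) * fs)
  }
  structure(list(power = P, freqs = freqs, times = centers,
                 taper_info = method, fs = fs, subject = ve$subject,
                 group = ve$group),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %s: %d freqs (%g-%g Hz) x %d times (%.2f..%.2f s)\n",
              x$taper_info$method, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.tfr <- function(x, baseline_win = NULL, ...) {
  z <- x$power
  lab <- "power"
  if (!is.null(baseline_win)) {
    bi <- time_index(x$times, baseline_win[1], baseline_win[2])
    z <- 10 * log10(z / rowMeans(z[, bi, drop = FALSE]))
    lab <- "dB vs baseline"
  }
  graphics::image(x$times, x$freqs, t(z), xlab = "time (s)",
                  ylab = "frequency (Hz)", main = lab, ...)
  invisible(x)
}

#' Multitaper time-frequency power (gamma band)
#'
#' Sliding-window DPSS multitaper spectrogram: default 40-70 Hz in 2 Hz
#' steps, 0.5 s windows sliding in 0.02 s steps with +/-7 Hz spectral
#' smoothing (time-bandwidth product 3.5, hence 6 tapers).  Power is
#' averaged over tapers and trials.
#'
#' @param ve A single-channel [epoch_set()] / virtual electrode.
#' @param freqs Analysis frequencies (Hz).
#' @param win_s Window length (s).
#' @param step_s Window step (s).
#' @param smooth_hz Half-bandwidth of spectral smoothing (Hz).
#' @return Object of class `tfr` (`power` freq x time, `freqs`, `times`).
#' @export
multitaper_tfr <- function(ve, freqs = seq(40, 70, 2), win_s = 0.5,
                           step_s = 0.02, smooth_hz = 7) {
  nw <- win_s * smooth_hz
  if (nw < 1) stop("smooth_hz * win_s must be >= 1")
  n_win <- round(win_s * ve$fs)
  k <- floor(2 * nw - 1)
  tapers <- dpss_tapers(n_win, nw, k)
  sliding_tfr(ve, freqs, win_s, step_s, tapers,
              list(method = "multitaper", nw = nw, n_tapers = k,
                   win_s = win_s, smooth_hz = smooth_hz))
}

#' Single Hanning-taper time-frequency power (alpha band)
#'
#' Default 8-13 Hz in 1 Hz steps with a sliding window stepping every
#' 0.1 s.  The window length defaults to 0.5 s: a window as short as the
#' step itself cannot resolve a 1 Hz frequency grid, so window length and
#' step are independent parameters.
#'
#' @inheritParams multitaper_tfr
#' @export
hanning_tfr <- function(ve, freqs = seq(8, 13, 1), win_s = 0.5,
                        step_s = 0.1) {
  n_win <- round(win_s * ve$fs)
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n_win))
  h <- matrix(h / sqrt(sum(h^2)), ncol = 1)
  sliding_tfr(ve, freqs, win_s, step_s, h,
              list(method = "hanning", win_s = win_s))
}

#' Baseline-normalised band power change in dB
#'
#' `10 log10` of the ratio of mean power in the stimulus window to mean
#' power in the baseline window, averaged over the band's frequency bins.
#'
#' @param tfr A [multitaper_tfr()] / [hanning_tfr()] result.
#' @param band `c(low, high)` Hz.
#' @param stim_win,base_win Windows (s relative to onset).
#' @return Object of class `band_change`: list with `subject`, `band`,
#'   `change_db`, `stim_win`, `base_win`.
#' @export
band_power_change <- function(tfr, band, stim_win = c(0.3, 1.5),
                              base_win = c(-1.5, -0.3)) {
  fi <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  si <- time_index(tfr$times, stim_win[1], stim_win[2])
  bi <- time_index(tfr$times, base_win[1], base_win[2])
  p_base <- mean(tfr$power[fi, bi])
  if (p_base <= 0) stop("zero baseline power")
  db <- 10 * log10(mean(tfr$power[fi, si]) / p_base)
  structure(list(subject = tfr$subject, band = band, change_db = db,
                 stim_win = stim_win, base_win = base_win),
            class = "band_change")
}

#' Peak frequency of the baseline-normalised power spectrum
#'
#' Computes the per-frequency dB change (stimulus vs baseline window) and
#' returns the frequency of its largest strict interior local extremum
#' within `band` (findpeaks semantics).  Peaks are detected on the signed
#' change when the mean band change is an increase (gamma-like responses)
#' and on the inverted change when it is a decrease (alpha-like
#' suppression), so the detected frequency always marks where the
#' stimulus-induced change is strongest.  If the spectrum is monotone
#' over the band, the band argmax of the (possibly inverted) change is
#' returned with `interior = FALSE`.
#'
#' @inheritParams band_power_change
#' @return List with `peak_hz`, `interior` (logical flag), `sign`
#'   (+1 increase / -1 decrease), `freqs`, `db` (the signed dB-change
#'   spectrum).
#' @export
peak_frequency <- function(tfr, band, stim_win = c(0.3, 1.5),
                           base_win = c(-1.5, -0.3)) {
  fi <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (length(fi) < 3) stop("need at least 3 frequency bins inside band")
  si <- time_index(tfr$times, stim_win[1], stim_win[2])
  bi <- time_index(tfr$times, base_win[1], base_win[2])
  db <- 10 * log10(rowMeans(tfr$power[fi, si, drop = FALSE]) /
                   rowMeans(tfr$power[fi, bi, drop = FALSE]))
  f <- tfr$freqs[fi]
  sgn <- if (mean(db) < 0) -1 else 1
  s <- sgn * db
  k <- length(s)
  interior <- which(s[2:(k - 1)] > s[1:(k - 2)] &
                    s[2:(k - 1)] > s[3:k]) + 1L
  if (length(interior)) {
    best <- interior[which.max(s[interior])]
    list(peak_hz = f[best], interior = TRUE, sign = sgn, freqs = f, db = db)
  } else {
    list(peak_hz = f[which.max(s)], interior = FALSE, sign = sgn,
         freqs = f, db = db)
  }
}

#' Absolute baseline band power
#'
#' Mean (absolute, not dB) power over the band and baseline window, for
#' checking that group differences are not driven by baseline offsets.
#'
#' @inheritParams band_power_change
#' @return Scalar power.
#' @export
baseline_band_power <- function(tfr, band, base_win = c(-1.5, -0.3)) {
  fi <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  bi <- time_index(tfr$times, base_win[1], base_win[2])
  mean(tfr$power[fi, bi])
}
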