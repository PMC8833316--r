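#' Instantaneous phase of a band-limited component
#'
#' Zero-phase Butterworth band-pass at `f_phase +/- half_bw` followed by
#' the analytic-signal (Hilbert) angle, computed on the full padded epoch
#' (cosine convention: phase 0 at signal peaks).
#'
#' @param ve Single-channel [epoch_set()].
#' @param f_phase Centre frequency (Hz).
#' @param half_bw Filter half-bandwidth (Hz, default 1, matching a 1 Hz
#'   phase-frequency grid).
#' @param order Butterworth order.
#' @return `trials x samples` matrix of phases (radians).
#' @export
extract_phase <- function(ve, f_phase, half_bw = 1, order = 4) {
  band_ok(ve, f_phase, half_bw)
  X <- t(ve_matrix(ve))
  gain <- butter_gain2(design_butter(ve$fs, f_phase - half_bw,
                                     f_phase + half_bw, order), nrow(X))
  t(Arg(analytic_band(X, gain)))
}

#' Instantaneous amplitude envelope of a band-limited component
#'
#' Zero-phase Butterworth band-pass at `f_amp +/- half_bw` followed by the
#' analytic-signal modulus.  For phase-amplitude coupling the half
#' bandwidth must be at least the highest phase frequency of interest, so
#' the modulation sidebands are retained (default 13 Hz).
#'
#' @param ve Single-channel [epoch_set()].
#' @param f_amp Centre frequency (Hz).
#' @param half_bw Filter half-bandwidth (Hz).
#' @param order Butterworth order.
#' @return `trials x samples` matrix of non-negative envelopes.
#' @export
extract_amplitude <- function(ve, f_amp, half_bw = 13, order = 4) {
  band_ok(ve, f_amp, half_bw)
  X <- t(ve_matrix(ve))
  gain <- butter_gain2(design_butter(ve$fs, f_amp - half_bw,
                                     f_amp + half_bw, order), nrow(X))
  t(Mod(analytic_band(X, gain)))
}

band_ok <- function(ve, f, half_bw) {
  if (f + half_bw >= ve$fs / 2)
    stop("band ", f, "+/-", half_bw, " Hz exceeds Nyquist (", ve$fs / 2, " Hz)")
  if (f - half_bw <= 0) stop("band ", f, "+/-", half_bw, " Hz reaches 0 Hz")
  dur <- diff(range(ve$times))
  if (dur * (2 * half_bw) < 2)
    stop("band too narrow (", 2 * half_bw, " Hz) for epoch length ", dur, " s")
  invisible(TRUE)
}

#' Amplitude-normalised mean vector length (PAC estimator)
#'
#' \deqn{\mathrm{PAC} = \frac{1}{\sqrt{N}}
#'   \frac{|\sum_t a_t e^{i\phi_t}|}{\sqrt{\sum_t a_t^2}},}
#' which lies in `[0, 1]` by the Cauchy-Schwarz inequality and is invariant
#' to positive rescaling of the amplitude.
#'
#' @param phase Phase series (radians).
#' @param amplitude Non-negative amplitude series, same length.
#' @return Scalar in `[0, 1]`.
#' @export
mvl_ozkurt <- function(phase, amplitude) {
  n <- length(phase)
  if (length(amplitude) != n) stop("phase and amplitude lengths differ")
  if (n < 2) stop("need at least 2 samples")
  if (any(amplitude < 0)) stop("amplitude must be >= 0")
  ss <- sum(amplitude^2)
  if (ss == 0) stop("all-zero amplitude")
  Mod(sum(amplitude * exp(1i * phase))) / sqrt(n * ss)
}

#' Phase-amplitude comodulogram
#'
#' For every (phase frequency, amplitude frequency) pair: per-trial phase
#' and envelope series are computed on the padded epoch, restricted to the
#' analysis window, concatenated across trials, and summarised by one
#' [mvl_ozkurt()] value.  Defaults follow an alpha-gamma design: phases
#' 7-13 Hz in 1 Hz steps, amplitudes 34-100 Hz in 2 Hz steps, window
#' 0.3-1.5 s after stimulus onset.
#'
#' @param ve Single-channel [epoch_set()].
#' @param window `c(start, end)` s relative to onset.
#' @param phase_freqs,amp_freqs Analysis grids (Hz).
#' @param phase_half_bw,amp_half_bw Filter half-bandwidths (Hz).
#' @param per_trial If `FALSE` (default) trials are concatenated after
#'   windowing and one MVL is computed per bin (maximising the sample
#'   count); if `TRUE` an MVL is computed per trial and averaged.
#' @return Object of class `comodulogram`: `values`
#'   (`phase_freqs x amp_freqs`), grids, `window`, `corrected = FALSE`.
#' @export
comodulogram <- function(ve, window = c(0.3, 1.5), phase_freqs = 7:13,
                         amp_freqs = seq(34, 100, 2), phase_half_bw = 1,
                         amp_half_bw = 13, per_trial = FALSE) {
  comodulogram_windows(ve, list(window), phase_freqs, amp_freqs,
                       phase_half_bw, amp_half_bw, per_trial)[[1]]
}

# Shared machinery: filter once per band, evaluate MVL in several windows.
comodulogram_windows <- function(ve, windows, phase_freqs, amp_freqs,
                                 phase_half_bw = 1, amp_half_bw = 13,
                                 per_trial = FALSE) {
  stopifnot(inherits(ve, "epoch_set"), n_channels(ve) == 1L)
  for (w in windows) {
    if (w[2] <= w[1]) stop("empty window")
    tol <- 1 / ve$fs + 1e-9
    if (w[1] < min(ve$times) + ve$pad_s - tol ||
        w[2] > max(ve$times) - ve$pad_s + tol)
      stop("window [", w[1], ", ", w[2], "] s outside the post-padding region")
  }
  idx <- lapply(windows, function(w) time_index(ve$times, w[1], w[2]))
  ph <- lapply(phase_freqs, function(f) {
    P <- extract_phase(ve, f, phase_half_bw)
    lapply(idx, function(ii) P[, ii, drop = FALSE])
  })
  am <- lapply(amp_freqs, function(f) {
    A <- extract_amplitude(ve, f, amp_half_bw)
    lapply(idx, function(ii) A[, ii, drop = FALSE])
  })
  bin_mvl <- function(P, A) {
    if (per_trial)
      mean(vapply(seq_len(nrow(P)), function(tr)
        mvl_ozkurt(P[tr, ], A[tr, ]), numeric(1)))
    else mvl_ozkurt(as.numeric(t(P)), as.numeric(t(A)))
  }
  lapply(seq_along(windows), function(wi) {
    v <- matrix(0, length(phase_freqs), length(amp_freqs),
                dimnames = list(phase_freqs, amp_freqs))
    for (i in seq_along(phase_freqs))
      for (j in seq_along(amp_freqs))
        v[i, j] <- bin_mvl(ph[[i]][[wi]], am[[j]][[wi]])
    structure(list(values = v, phase_freqs = phase_freqs,
                   amp_freqs = amp_freqs, window = windows[[wi]],
                   corrected = FALSE, subject = ve$subject, group = ve$group),
              class = "comodulogram")
  })
}

#' Baseline-corrected comodulogram
#'
#' Element-wise difference between the stimulus-window and an equal-length
#' baseline-window comodulogram; corrected values lie in `[-1, 1]` and are
#' near zero when coupling is stationary across the epoch.
#'
#' @inheritParams comodulogram
#' @param stim_win,base_win Equal-duration windows (s relative to onset).
#' @return `comodulogram` with `corrected = TRUE`.
#' @export
corrected_comodulogram <- function(ve, stim_win = c(0.3, 1.5),
                                   base_win = c(-1.5, -0.3),
                                   phase_freqs = 7:13,
                                   amp_freqs = seq(34, 100, 2),
                                   phase_half_bw = 1, amp_half_bw = 13,
                                   per_trial = FALSE) {
  if (abs(diff(stim_win) - diff(base_win)) > 1e-9)
    stop("stimulus and baseline windows must have equal duration")
  both <- comodulogram_windows(ve, list(stim_win, base_win), phase_freqs,
                               amp_freqs, phase_half_bw, amp_half_bw,
                               per_trial)
  out <- both[[1]]
  out$values <- both[[1]]$values - both[[2]]$values
  out$corrected <- TRUE
  out$base_win <- base_win
  out
}

#' @export
print.comodulogram <- function(x, ...) {
  pk <- arrayInd(which.max(x$values), dim(x$values))
  cat(sprintf("<comodulogram%s> %d phase x %d amp bins; max %.4f at (%g Hz, %g Hz)\n",
              if (x$corrected) ", baseline-corrected" else "",
              length(x$phase_freqs), length(x$amp_freqs), max(x$values),
              x$phase_freqs[pk[1]], x$amp_freqs[pk[2]]))
  invisible(x)
}

#' @export
plot.comodulogram <- function(x, ...) {
  graphics::image(x$phase_freqs, x$amp_freqs, x$values,
                  xlab = "phase frequency (Hz)",
                  ylab = "amplitude frequency (Hz)",
                  main = if (x$corrected) "PAC (corrected)" else "PAC", ...)
  invisible(x)
}
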