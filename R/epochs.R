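#' Trial-epoched MEG data container
#'
#' `epoch_set` is the package's interchange object: a numeric array of
#' `trials x channels x samples`, a time axis in seconds relative to
#' stimulus onset, the sampling rate, and subject/group metadata.  Epochs
#' generated by the simulator or by [epoch_continuous()] carry `pad_s`
#' seconds of padding on either side of the analysis window; padding is kept
#' through filtering and time-frequency decomposition (so edge transients
#' never enter a windowed average) and trimmed afterwards.
#'
#' @param data Numeric array `trials x channels x samples` (a
#'   `trials x samples` matrix is promoted to one channel).
#' @param times Numeric vector of sample times (s), zero at stimulus onset.
#' @param fs Sampling rate (Hz).
#' @param subject Subject identifier.
#' @param group Group label (e.g. `"patient"`, `"control"`).
#' @param pad_s Padding retained on each side of the analysis window (s).
#' @param truth Optional named list of ground-truth simulation parameters
#'   (e.g. `gamma_change_db`, `coupling_m`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, fs, subject = "s01", group = NA_character_,
                      pad_s = 0, truth = list()) {
  if (is.matrix(data)) data <- array(data, c(nrow(data), 1L, ncol(data)))
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(times), fs > 0)
  if (!all(is.finite(data))) stop("epoch data contain non-finite values")
  structure(
    list(data = data, times = as.numeric(times), fs = fs,
         subject = subject, group = group, pad_s = pad_s, truth = truth),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s (group %s): %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject, x$group, d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %.3f .. %.3f s (pad %.2f s each side)\n",
              min(x$times), max(x$times), x$pad_s))
  if (length(x$truth))
    cat("  ground truth:", paste(names(x$truth),
        vapply(x$truth, function(v) paste(signif(unlist(v), 4), collapse = ","),
               ""), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

n_trials <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

#' Single-channel virtual electrode
#'
#' A `virtual_electrode` is an `epoch_set` with exactly one channel,
#' produced by projecting sensor epochs through a beamformer spatial filter
#' ([virtual_electrode()]) or simulated directly.
#'
#' @param x An `epoch_set` with one channel, or a `trials x samples` matrix.
#' @inheritParams epoch_set
#' @return Object of class `c("virtual_electrode", "epoch_set")`.
#' @export
as_virtual_electrode <- function(x, times = NULL, fs = NULL, ...) {
  if (is.matrix(x)) x <- epoch_set(x, times, fs, ...)
  stopifnot(inherits(x, "epoch_set"), n_channels(x) == 1L)
  class(x) <- unique(c("virtual_electrode", class(x)))
  x
}

# trials x samples matrix view of a single-channel epoch_set
ve_matrix <- function(x) {
  stopifnot(n_channels(x) == 1L)
  matrix(x$data[, 1L, ], nrow = n_trials(x))
}

# indices of the time axis inside [t0, t1] (closed)
time_index <- function(times, t0, t1) {
  idx <- which(times >= t0 - 1e-9 & times <= t1 + 1e-9)
  if (!length(idx)) stop("window [", t0, ", ", t1, "] s outside epoch time axis")
  idx
}
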