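#' Band-limited sensor covariance over a time window
#'
#' Band-passes each trial (zero-phase Butterworth on the padded epoch),
#' extracts the window, and averages the per-trial sample covariance
#' (outer-product, normalised by sample count) over trials.
#'
#' @param epochs Multi-channel [epoch_set()].
#' @param t_start,t_end Window (s relative to onset).
#' @param band `c(low, high)` Hz, or `NULL` for broadband.
#' @param order Butterworth order.
#' @return Symmetric `channels x channels` covariance matrix.
#' @export
covariance_window <- function(epochs, t_start, t_end, band = NULL, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"), t_start < t_end)
  if (!is.null(band) && (t_end - t_start) < 3 / band[1])
    warning("window shorter than 3 cycles of ", band[1], " Hz")
  n <- n_samples(epochs)
  nt <- n_trials(epochs); nc <- n_channels(epochs)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)
  if (!is.null(band)) {
    gain <- butter_gain2(design_butter(epochs$fs, band[1], band[2], order), n)
    flat <- apply_gain(flat, gain)
  }
  idx <- time_index(epochs$times, t_start, t_end)
  C <- matrix(0, nc, nc)
  for (tr in seq_len(nt)) {
    X <- matrix(flat[idx, (0:(nc - 1)) * nt + tr], ncol = nc)  # samples x ch
    C <- C + crossprod(X) / length(idx)
  }
  C <- C / nt
  (C + t(C)) / 2
}

#' Diagonal-loading regularisation
#'
#' `C_reg = C + (lambda_pct/100) * mean(diag(C)) * I`.
#'
#' @param C Square symmetric covariance matrix.
#' @param lambda_pct Regularisation as a percentage of the mean sensor
#'   variance (default 5).
#' @return Regularised covariance.
#' @export
regularize <- function(C, lambda_pct = 5) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C),
            isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
  if (lambda_pct < 0) stop("lambda_pct must be >= 0")
  C + (lambda_pct / 100) * mean(diag(C)) * diag(nrow(C))
}

#' LCMV spatial filter for one grid point
#'
#' Linearly constrained minimum variance beamformer weights
#' \deqn{w = (l^T C^{-1} l)^{-1} C^{-1} l} for the fixed-orientation
#' lead-field column `l`, satisfying the unit-gain constraint
#' \eqn{w^T l = 1}.
#'
#' @param model A `source_model`.
#' @param grid_index Grid point index.
#' @param C_reg Regularised (invertible) sensor covariance.
#' @param lambda_pct Recorded regularisation level (metadata only).
#' @return Object of class `spatial_filter` with fields `weights`,
#'   `grid_index`, `lambda_pct`.
#' @export
lcmv_filter <- function(model, grid_index, C_reg, lambda_pct = NA_real_) {
  l <- model$leadfield[, grid_index]
  if (all(l == 0)) stop("zero lead-field column at grid point ", grid_index)
  Cinv_l <- solve(C_reg, l)
  w <- Cinv_l / sum(l * Cinv_l)
  stopifnot(abs(sum(w * l) - 1) < 1e-6)
  structure(list(weights = as.numeric(w), grid_index = grid_index,
                 lambda_pct = lambda_pct), class = "spatial_filter")
}

#' Source power-change map
#'
#' For each grid point, computes a common LCMV filter from the band-limited
#' covariance over the combined baseline + stimulus windows (regularised by
#' `lambda_pct`), then the stimulus/baseline power ratio through that
#' filter in dB: `10 log10(w' C_stim w / w' C_base w)`.
#'
#' @param epochs Multi-channel [epoch_set()].
#' @param model A `source_model`.
#' @param band `c(low, high)` Hz.
#' @param stim_win,base_win Windows (s) relative to onset.
#' @param lambda_pct Regularisation percentage.
#' @return Object of class `source_map`: list with `db` (per grid point),
#'   `band`, `model`, `filters` (list of `spatial_filter`).
#' @export
source_power_map <- function(epochs, model, band, stim_win = c(0.3, 1.5),
                             base_win = c(-1.5, -0.3), lambda_pct = 5) {
  C_base <- covariance_window(epochs, base_win[1], base_win[2], band)
  C_stim <- covariance_window(epochs, stim_win[1], stim_win[2], band)
  C_common <- regularize((C_base + C_stim) / 2, lambda_pct)
  ng <- ncol(model$leadfield)
  db <- numeric(ng)
  filters <- vector("list", ng)
  for (g in seq_len(ng)) {
    f <- lcmv_filter(model, g, C_common, lambda_pct)
    w <- f$weights
    db[g] <- 10 * log10((w %*% C_stim %*% w) / (w %*% C_base %*% w))
    filters[[g]] <- f
  }
  structure(list(db = db, band = band, model = model, filters = filters,
                 stim_win = stim_win, base_win = base_win,
                 lambda_pct = lambda_pct), class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> band %g-%g Hz, %d grid points, max %+.2f dB at #%d\n",
              x$band[1], x$band[2], length(x$db), max(x$db), which.max(x$db)))
  invisible(x)
}

#' Select the ROI grid point with the largest power increase
#'
#' Argmax of the dB change restricted to the model's ROI mask; ties are
#' broken deterministically by the lowest grid index.
#'
#' @param map A [source_power_map()] result.
#' @param model Optional `source_model` (defaults to the map's own).
#' @return Grid point index.
#' @export
select_roi_peak <- function(map, model = map$model) {
  roi <- which(model$roi_mask)
  if (!length(roi)) stop("empty ROI mask")
  vals <- map$db[roi]
  if (all(is.na(vals))) stop("all-NaN power map in ROI")
  roi[which.max(vals)]                        # which.max takes first on ties
}

#' Extract a virtual electrode
#'
#' Projects broadband (unfiltered-band) sensor epochs through one grid
#' point's spatial filter, yielding a single-channel trials x time series.
#' The weights are typically derived from band-limited covariance (e.g.
#' gamma) and applied here to broadband data.
#'
#' @param epochs Multi-channel [epoch_set()].
#' @param filter A `spatial_filter`.
#' @return A [as_virtual_electrode()] object.
#' @export
virtual_electrode <- function(epochs, filter) {
  w <- filter$weights
  if (length(w) != n_channels(epochs))
    stop("filter has ", length(w), " weights but epochs have ",
         n_channels(epochs), " channels")
  nt <- n_trials(epochs); ns <- n_samples(epochs)
  out <- matrix(0, nt, ns)
  for (tr in seq_len(nt))
    out[tr, ] <- w %*% matrix(epochs$data[tr, , ], nrow = length(w))
  ve <- epoch_set(out, epochs$times, epochs$fs, subject = epochs$subject,
                  group = epochs$group, pad_s = epochs$pad_s,
                  truth = epochs$truth)
  as_virtual_electrode(ve)
}
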