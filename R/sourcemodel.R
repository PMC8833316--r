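#' Toy source model for beamformer validation
#'
#' A deliberately simple forward model: `n_sensors` sensors on a spherical
#' cap above a cubic `grid_dim^3` source grid, with a fixed-orientation
#' scalar lead field given by smooth distance decay
#' \eqn{L_{sg} = 1/(d_{sg}^2 + \epsilon)}.  A posterior-inferior block of
#' grid points is labelled as the region of interest (the "calcarine"
#' stand-in).  This is sufficient to exercise LCMV unit gain and
#' point-source recovery; it makes no claim to head-model physics.
#'
#' @param n_sensors Number of sensors on the cap.
#' @param grid_dim Sources per axis (grid has `grid_dim^3` points).
#' @param eps Lead-field regularisation length-squared.
#' @return Object of class `source_model` with fields `sensor_positions`
#'   (`n_sensors x 3`), `grid_points` (`n_grid x 3`), `leadfield`
#'   (`n_sensors x n_grid`), `roi_mask` (logical per grid point).
#' @export
toy_source_model <- function(n_sensors = 30, grid_dim = 4, eps = 0.05) {
  stopifnot(n_sensors >= 4, grid_dim >= 2)
  # Fibonacci-spiral cap on the upper hemisphere, radius 1.1
  i <- seq_len(n_sensors)
  z <- 0.15 + 0.85 * (i - 0.5) / n_sensors
  th <- pi * (3 - sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  sensors <- 1.1 * cbind(r * cos(th), r * sin(th), z)
  ax <- seq(-0.6, 0.6, length.out = grid_dim)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))[, 3:1]
  colnames(grid) <- c("x", "y", "z")
  d2 <- outer(rowSums(sensors^2), rep(1, nrow(grid))) +
        outer(rep(1, n_sensors), rowSums(grid^2)) -
        2 * sensors %*% t(grid)
  lf <- 1 / (d2 + eps)
  # ROI: posterior (most negative y), inferior (most negative z) corner block
  half <- ax[seq_len(ceiling(grid_dim / 2))]
  roi <- grid[, "y"] %in% half & grid[, "z"] %in% half
  stopifnot(any(roi), all(is.finite(lf)), all(colSums(abs(lf)) > 0))
  structure(list(sensor_positions = sensors, grid_points = grid,
                 leadfield = lf, roi_mask = roi),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %d sensors, %d grid points (%d in ROI)\n",
              nrow(x$sensor_positions), nrow(x$grid_points), sum(x$roi_mask)))
  invisible(x)
}

#' Project source epochs to synthetic sensors
#'
#' Forward simulation: sensor data are the lead-field column at
#' `source_index` times the source time series, plus independent Gaussian
#' sensor noise.
#'
#' @param source_epochs Single-channel [epoch_set()] with the source series.
#' @param model A [toy_source_model()] (or compatible `source_model`).
#' @param source_index Grid point index of the active source.
#' @param sensor_noise_amp SD of i.i.d. Gaussian sensor noise.
#' @param seed Optional seed for the sensor noise.
#' @return Multi-channel [epoch_set()] (`n_sensors` channels).
#' @export
project_to_sensors <- function(source_epochs, model, source_index,
                               sensor_noise_amp = 0, seed = NULL) {
  stopifnot(inherits(source_epochs, "epoch_set"),
            n_channels(source_epochs) == 1L)
  ng <- ncol(model$leadfield)
  if (source_index < 1 || source_index > ng)
    stop("source_index must be in 1..", ng)
  if (!is.null(seed)) set.seed(seed)
  lf <- model$leadfield[, source_index]
  src <- ve_matrix(source_epochs)                    # trials x samples
  nt <- nrow(src); ns <- ncol(src); nc <- length(lf)
  dat <- array(0, c(nt, nc, ns))
  for (tr in seq_len(nt)) {
    x <- outer(lf, src[tr, ])
    if (sensor_noise_amp > 0)
      x <- x + matrix(stats::rnorm(nc * ns, sd = sensor_noise_amp), nc, ns)
    dat[tr, , ] <- x
  }
  epoch_set(dat, source_epochs$times, source_epochs$fs,
            subject = source_epochs$subject, group = source_epochs$group,
            pad_s = source_epochs$pad_s, truth = c(source_epochs$truth,
            list(source_index = source_index)))
}
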