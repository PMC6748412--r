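# Uniformly sampled time series: the common currency of the simulator, the
# filter, and file I/O.

#' Construct a trajectory
#'
#' @param values numeric vector of positions (state or observation units).
#' @param dt sampling interval in seconds.
#' @param t0 time of the first sample.
#' @param meta named list of provenance (preset, seed, fine step, ...).
#' @return an object of class `ipc_trajectory`.
#' @export
ipc_trajectory <- function(values, dt, t0 = 0, meta = list()) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("a trajectory needs at least 2 samples")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  structure(list(values = values, dt = dt, t0 = t0, meta = meta),
            class = "ipc_trajectory")
}

#' @export
print.ipc_trajectory <- function(x, ...) {
  cat(sprintf("ipc_trajectory: %d samples at %g Hz (%.4g s), t0 = %g\n",
              length(x$values), 1 / x$dt, (length(x$values) - 1) * x$dt, x$t0))
  if (!is.null(x$meta$preset)) cat("  preset:", x$meta$preset, "\n")
  invisible(x)
}

#' @export
as.data.frame.ipc_trajectory <- function(x, ...) {
  data.frame(time = x$t0 + (seq_along(x$values) - 1) * x$dt,
             value = x$values)
}

#' Times of a trajectory's samples
#' @param traj an `ipc_trajectory`.
#' @return numeric vector of sample times.
#' @export
trajectory_times <- function(traj) {
  traj$t0 + (seq_along(traj$values) - 1) * traj$dt
}

#' Downsample a trajectory by decimation
#'
#' Keeps every k-th sample starting at the first one; no averaging or
#' anti-alias filtering is applied (mirroring the mapping of an analogue
#' process to discrete measurements).
#'
#' @param traj an `ipc_trajectory`.
#' @param target_hz target sampling rate; the target interval must be an
#'   integer multiple of the source interval.
#' @return the decimated `ipc_trajectory`.
#' @export
downsample <- function(traj, target_hz) {
  stopifnot(inherits(traj, "ipc_trajectory"))
  ratio <- 1 / (target_hz * traj$dt)
  k <- round(ratio)
  if (k < 1 || abs(ratio - k) > 1e-6 * k) {
    stop("target interval must be an integer multiple of the source interval")
  }
  if (k == 1) return(traj)
  idx <- seq(1, length(traj$values), by = k)
  meta <- traj$meta
  meta$downsample_factor <- c(meta$downsample_factor, k)
  ipc_trajectory(traj$values[idx], traj$dt * k, traj$t0, meta)
}

#' Turn a state trajectory into noisy observations
#'
#' Applies the measurement model `y = x + mu + sqrt(eps) * N(0, 1)` sample
#' by sample.
#'
#' @param traj an `ipc_trajectory` in state units.
#' @param eps measurement-error variance (`>= 0`).
#' @param mu sway origin offset.
#' @param seed optional integer seed.
#' @return an `ipc_trajectory` in observation units.
#' @export
observe <- function(traj, eps, mu = 0, seed = NULL) {
  stopifnot(inherits(traj, "ipc_trajectory"), eps >= 0)
  if (!is.null(seed)) set.seed(seed)
  y <- traj$values + mu
  if (eps > 0) y <- y + sqrt(eps) * rnorm(length(y))
  meta <- traj$meta
  meta$eps <- eps
  meta$mu <- mu
  ipc_trajectory(y, traj$dt, traj$t0, meta)
}
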