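# Fine-step Euler-Maruyama simulation of the IPC stochastic delay
# differential equation, plus the six named parameter presets used in the
# recovery studies.

#' Simulate the IPC stochastic delay differential equation
#'
#' Integrates the tilt-angle dynamics by Euler-Maruyama at a fine step with a
#' ring delay buffer. The activation condition is re-evaluated at every fine
#' step from the buffered lagged state; the pre-history for `t < tau` holds
#' the initial state constant. Process noise enters at the acceleration level
#' with intensity `sigma` (the same convention as the filter's `Q`), so
#' simulator and estimator are mutually consistent.
#'
#' @param params [ipc_params()]. The measurement-error variance `eps` is NOT
#'   applied here; use [observe()] for that.
#' @param constants [ipc_constants()].
#' @param duration length of the series in seconds.
#' @param fine_dt integration step, s (default `1e-5`).
#' @param x0,xdot0 initial tilt angle (rad) and velocity (rad/s).
#' @param seed optional integer seed (noise is drawn from R's RNG, so
#'   identical seeds give bit-identical trajectories).
#' @param noiseless if `TRUE`, the stochastic term is zeroed (deterministic
#'   trajectory).
#' @param record_hz optional recording rate; when supplied, only every k-th
#'   fine step is stored (`k = 1 / (record_hz * fine_dt)`, which must be an
#'   integer), saving memory on long runs. Default records every fine step.
#' @param keep_velocity if `TRUE`, the recorded angular velocities are kept
#'   in `meta$velocity`.
#' @return an `ipc_trajectory` in state units (rad).
#' @export
ipc_simulate <- function(params, constants = ipc_constants(), duration,
                         fine_dt = 1e-5, x0 = 0, xdot0 = 0, seed = NULL,
                         noiseless = FALSE, record_hz = NULL,
                         keep_velocity = FALSE) {
  stopifnot(inherits(params, "ipc_params"), inherits(constants, "ipc_constants"))
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be positive")
  if (!is.finite(fine_dt) || fine_dt <= 0) stop("'fine_dt' must be positive")
  record_every <- 1L
  if (!is.null(record_hz)) {
    ratio <- 1 / (record_hz * fine_dt)
    record_every <- as.integer(round(ratio))
    if (record_every < 1 || abs(ratio - record_every) > 1e-6 * record_every) {
      stop("'record_hz' interval must be an integer multiple of 'fine_dt'")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  sim <- cpp_simulate(duration, fine_dt,
                      params$K, params$B, params$P, params$D, params$a,
                      params$r, params$tau, params$sigma,
                      constants$mass, constants$com_height, constants$gravity,
                      constants$inertia,
                      x0, xdot0, noiseless, record_every, keep_velocity)
  meta <- list(fine_dt = fine_dt, seed = seed, noiseless = noiseless,
               x0 = x0, xdot0 = xdot0, record_every = record_every,
               params = unclass(params))
  if (keep_velocity) meta$velocity <- sim$vel
  ipc_trajectory(sim$pos, fine_dt * record_every, 0, meta)
}

#' Named parameter presets for the recovery studies
#'
#' Six structural parameterizations spanning qualitatively different sway
#' regimes: the Asai et al. replication set, its low- and high-noise
#' variants, a passively dominated and an actively dominated configuration,
#' and a stationary random-walk ("rambling and trembling") regime.
#'
#' @return a named list of [ipc_params()] objects.
#' @export
ipc_presets <- function() {
  list(
    "Asai et al." = ipc_params(K = 0.80, B = 4, P = 0.25, D = 10,
                               a = 0.62, r = 0.40, tau = 0.20, sigma = 0.20,
                               eps = 1e-4),
    "Low Noise" = ipc_params(K = 0.80, B = 4, P = 0.25, D = 10,
                             a = 0.62, r = 0.40, tau = 0.20, sigma = 0.05,
                             eps = 1e-4),
    "High Noise" = ipc_params(K = 0.80, B = 4, P = 0.25, D = 10,
                              a = 0.62, r = 0.40, tau = 0.20, sigma = 1.00,
                              eps = 1e-4),
    "Passive Control" = ipc_params(K = 0.95, B = 4, P = 0.15, D = 10,
                                   a = 0.50, r = 0.70, tau = 0.20,
                                   sigma = 0.20, eps = 1e-4),
    "Active Control" = ipc_params(K = 0.75, B = 4, P = 0.70, D = 120,
                                  a = 0.80, r = 0.20, tau = 0.20,
                                  sigma = 0.20, eps = 1e-4),
    "Rambling and Trembling" = ipc_params(K = 0.98, B = 500, P = 0.20,
                                          D = -50, a = 0.45, r = 0.05,
                                          tau = 0.20, sigma = 2.00,
                                          eps = 1e-4)
  )
}

#' Look up a preset by (partial, case-insensitive) name
#' @param name preset name, e.g. `"asai"`, `"Passive Control"`.
#' @return an [ipc_params()] object with attribute `"preset"`.
#' @export
ipc_preset <- function(name) {
  presets <- ipc_presets()
  hit <- grep(tolower(name), tolower(names(presets)), fixed = TRUE)
  if (length(hit) != 1) {
    stop("preset '", name, "' does not uniquely match one of: ",
         paste(names(presets), collapse = ", "))
  }
  p <- presets[[hit]]
  attr(p, "preset") <- names(presets)[hit]
  p
}
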