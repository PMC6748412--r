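# Structural parameters, physical constants, model variants, and the
# continuous state-space representation with its discretization.

VARIANTS <- c("ISDDE", "SDDE", "SDE")

variant_code <- function(variant) {
  match(match.arg(toupper(variant), VARIANTS), VARIANTS) - 1L
}

#' Physical constants of the single-link pendulum
#'
#' @param mass body mass in kg.
#' @param com_height distance of the center of mass from the ankle, in m. For
#'   a standing subject of stature `H`, the conventional value is `0.51 * H`
#'   (see [com_height_from_stature()]). The default pendulum (60 kg,
#'   h = 1 m, point-mass inertia 60 kg m^2) is the classic single-link
#'   reference configuration of the intermittent-control literature and is
#'   the one used by the simulation studies.
#' @param gravity gravitational acceleration, m/s^2.
#' @param inertia rotational inertia about the ankle, kg m^2. Defaults to the
#'   point-mass value `mass * com_height^2`, which reduces the gravitational
#'   stiffness `m*g*h/I` to `g/h`.
#' @return an object of class `ipc_constants`.
#' @export
ipc_constants <- function(mass = 60, com_height = 1, gravity = 9.81,
                          inertia = NULL) {
  if (is.null(inertia)) inertia <- mass * com_height^2
  vals <- c(mass = mass, com_height = com_height, gravity = gravity,
            inertia = inertia)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("physical constants must all be finite and strictly positive")
  }
  structure(as.list(vals), class = "ipc_constants")
}

#' Pendulum height from stature
#'
#' Applies the standard anthropometric ratio: the center of mass of an
#' upright adult sits at about 51% of stature.
#'
#' @param stature standing height in m.
#' @return center-of-mass height `h` in m.
#' @export
com_height_from_stature <- function(stature) 0.51 * stature

#' Structural parameters of the IPC model
#'
#' @param K intrinsic upright stiffness, as a fraction of the gravitational
#'   toppling stiffness `m*g*h` (dimensionless).
#' @param B passive joint friction, N m s / rad.
#' @param P active proportional gain, as a fraction of `m*g*h`.
#' @param D active derivative gain, N m s / rad.
#' @param a fraction parameterizing the switching-line angle `a*pi`; must lie
#'   in `[0, 1]`. `a = 0.5` is the singular vertical-line geometry and is
#'   representable (see [alpha_from_a()]).
#' @param r insensitivity radius in the phase plane, rad.
#' @param tau feedback delay, s.
#' @param sigma process-noise intensity at the acceleration level (the
#'   stochastic torque enters as `sigma * sqrt(dt) * N(0,1)`).
#' @param eps measurement-error variance, in squared observation units.
#' @return an object of class `ipc_params`.
#' @export
ipc_params <- function(K, B, P = 0, D = 0, a = 0, r = 0, tau = 0,
                       sigma = 0, eps = 0) {
  p <- list(K = K, B = B, P = P, D = D, a = a, r = r, tau = tau,
            sigma = sigma, eps = eps)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    stop("all IPC parameters must be finite scalars")
  }
  if (a < 0 || a > 1) stop("'a' must lie in [0, 1]")
  if (r < 0) stop("'r' must be non-negative")
  if (tau < 0) stop("'tau' must be non-negative")
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (eps < 0) stop("'eps' must be non-negative")
  structure(p, class = "ipc_params")
}

#' Trial-specific nuisance parameters
#'
#' Each observed trial carries its own initial position and velocity, a
#' quadratic backward-extrapolation coefficient (used only by the delayed
#' variants to reconstruct lagged states before the first observation), and
#' a sway origin offset on the observation scale.
#'
#' @param x0,xdot0 initial state.
#' @param xddot0 quadratic extrapolation coefficient; ignored when `tau = 0`
#'   and by the SDE variant.
#' @param mu sway origin offset added to the measurement equation.
#' @return an object of class `ipc_nuisance`.
#' @export
ipc_nuisance <- function(x0 = 0, xdot0 = 0, xddot0 = 0, mu = 0) {
  structure(list(x0 = x0, xdot0 = xdot0, xddot0 = xddot0, mu = mu),
            class = "ipc_nuisance")
}

#' Switching-line slope from the angle fraction
#'
#' The switching line through the phase-plane origin makes angle `a * pi`
#' with the position axis; its slope is `tan(a * pi)`. `a = 0.5` gives a
#' vertical line, for which no finite slope exists: this function signals an
#' error, and the filter/simulator internally represent that geometry as the
#' limit from above (active everywhere outside the insensitivity radius).
#'
#' @param a angle fraction in `[0, 1]`, `a != 0.5`.
#' @return the slope `tan(a * pi)`.
#' @export
alpha_from_a <- function(a) {
  if (any(a < 0 | a > 1)) stop("'a' must lie in [0, 1]")
  if (any(abs(a - 0.5) < 1e-12)) {
    stop("a = 0.5 gives a vertical (singular) switching line; ",
         "handle this geometry explicitly")
  }
  tan(a * pi)
}

# internal: slope including the vertical-line convention used by the filter
alpha_internal <- function(a) {
  if (abs(a - 0.5) < 1e-12) -1e16 else tan(a * pi)
}

#' Continuous state-space form of an IPC variant
#'
#' Builds the drift matrices of the linear(-per-regime) state-space model
#' `dx = (A x + A_tau x(t - tau)) dt + noise`:
#' `A = [[0, 1], [m*g*h*(1-K)/I, -B/I]]` and
#' `A_tau = [[0, 0], [-m*g*h*P/I, -D/I]]` (zeroed for the SDE variant).
#' The process-noise intensity matrix is `Q = diag(0, sigma^2)` and the
#' measurement model is `H = [1, 0]`, `R = eps`.
#'
#' @param params [ipc_params()].
#' @param constants [ipc_constants()].
#' @param variant one of `"ISDDE"`, `"SDDE"`, `"SDE"`.
#' @return an object of class `ipc_state_space` with elements `A`, `Atau`,
#'   `Q`, `H`, `R`, `alpha`, `r`, `s` and `variant`.
#' @export
ipc_state_space <- function(params, constants = ipc_constants(),
                            variant = "ISDDE") {
  stopifnot(inherits(params, "ipc_params"), inherits(constants, "ipc_constants"))
  variant <- match.arg(toupper(variant), VARIANTS)
  mgh <- constants$mass * constants$gravity * constants$com_height
  I <- constants$inertia
  A <- matrix(c(0, mgh * (1 - params$K) / I, 1, -params$B / I), 2, 2)
  if (variant == "SDE") {
    Atau <- matrix(0, 2, 2)
  } else {
    Atau <- matrix(c(0, -mgh * params$P / I, 0, -params$D / I), 2, 2)
  }
  structure(list(
    A = A, Atau = Atau,
    Q = matrix(c(0, 0, 0, params$sigma^2), 2, 2),
    H = matrix(c(1, 0), 1, 2),
    R = matrix(params$eps, 1, 1),
    alpha = if (variant == "ISDDE") alpha_internal(params$a) else NA_real_,
    r = params$r, s = 1, tau = params$tau, variant = variant),
    class = "ipc_state_space")
}

#' Discretize the state-space model over an interval
#'
#' Computes `Ad = expm(A * dt)`, the delayed transition
#' `Ataud = [integral_0^dt expm(A s) ds] %*% Atau` via an augmented
#' block matrix exponential (no inversion of `A`, so `K = 1` is legal), and
#' the process-noise covariance `Qd = integral_0^dt expm(A s) Q expm(A s)' ds`
#' by the Van Loan matrix-fraction construction.
#'
#' @param model an [ipc_state_space()] object.
#' @param dt interval length in seconds, `> 0`.
#' @param active if `FALSE`, the delayed transition is zeroed (inactive
#'   regime).
#' @return an object of class `ipc_discretized` with `Ad`, `Ataud`, `Qd`,
#'   `dt`.
#' @export
ipc_discretize <- function(model, dt, active = TRUE) {
  stopifnot(inherits(model, "ipc_state_space"))
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a positive scalar")
  }
  d <- cpp_kalman_integrate(model$A, model$Atau, model$Q, dt)
  if (!active) d$Ataud <- matrix(0, 2, 2)
  structure(list(Ad = d$Ad, Ataud = d$Ataud, Qd = d$Qd, dt = dt),
            class = "ipc_discretized")
}

#' @export
print.ipc_params <- function(x, ...) {
  cat("IPC structural parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.ipc_constants <- function(x, ...) {
  cat(sprintf("Pendulum constants: m = %g kg, h = %g m, g = %g m/s^2, I = %g kg m^2\n",
              x$mass, x$com_height, x$gravity, x$inertia))
  invisible(x)
}
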