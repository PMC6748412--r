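# Delayed switching Kalman filter: lag interpolation, backward extrapolation
# of initial conditions, single- and two-step prediction across activation
# thresholds, measurement correction, and the -2 log-likelihood by
# prediction-error decomposition.
#
# The production path is the compiled filter (`engine = "cpp"`); an R
# reference filter built from the exported step functions is kept as a
# structural cross-check (`engine = "r"`).

#' Interpolated lagged state from a buffer of corrected means
#'
#' Returns the state `lam` steps before row `i` of a chronologically ordered
#' buffer of corrected (posterior) state means, by linear interpolation
#' between the bracketing rows. The default mode interpolates between
#' `i - floor(lam)` and `i - ceiling(lam)`; `compat = TRUE` reproduces the
#' printed formula whose sign extrapolates away from the older sample
#' instead (the two agree whenever `lam` is an integer).
#'
#' @param buffer numeric matrix with one row per time point and two columns
#'   (position, velocity).
#' @param i current row index (1-based).
#' @param lam lag expressed in sampling steps (`tau / dt`), `>= 0`.
#' @param compat use the paper-compatibility sign.
#' @return numeric length-2 state.
#' @export
lagged_state <- function(buffer, i, lam, compat = FALSE) {
  buffer <- as.matrix(buffer)
  if (nrow(buffer) == 0) stop("empty delay buffer")
  if (lam < 0) stop("'lam' must be non-negative")
  clamp <- function(j) min(max(j, 1L), i)
  newer <- clamp(i - floor(lam))
  older <- clamp(i - ceiling(lam))
  f <- lam - floor(lam)
  if (older == newer || f == 0) return(buffer[newer, ])
  if (compat) {
    buffer[newer, ] + (buffer[newer, ] - buffer[older, ]) * f
  } else {
    buffer[newer, ] + (buffer[older, ] - buffer[newer, ]) * f
  }
}

#' Backward extrapolation of lagged states before the first observation
#'
#' For query times `t <= tau` the lagged state is unobserved; it is
#' reconstructed by a quadratic extrapolation through the trial's initial
#' values: position `x0 + xdot0*(t - tau) + xddot0*(t - tau)^2` and velocity
#' `xdot0 + 2*xddot0*(t - tau)`. `xddot0` is a fitted coefficient (there is
#' no 1/2 on the quadratic term), not a literal acceleration.
#'
#' @param nuisance [ipc_nuisance()].
#' @param t base time of the query (s), `t <= tau`.
#' @param tau feedback delay (s).
#' @return numeric length-2 state at time `t - tau`.
#' @export
extrapolate_initial <- function(nuisance, t, tau) {
  s <- t - tau
  c(nuisance$x0 + nuisance$xdot0 * s + nuisance$xddot0 * s^2,
    nuisance$xdot0 + 2 * nuisance$xddot0 * s)
}

#' One prediction step of the delayed filter
#'
#' Propagates a Gaussian state over one sampling interval. The lagged
#' endpoints `u` (at `t - tau`) and `v` (at `t + dt - tau`) decide the
#' regime: if no activation threshold is crossed, a single step is taken
#' (with the delayed input evaluated at the interval end when active); if
#' the segment crosses a threshold, the step is split at the interpolated
#' crossing into an active and an inactive piece. The lagged covariance is
#' approximated by the current corrected covariance throughout.
#'
#' @param state list with `mean` (length 2) and `cov` (2x2).
#' @param u,v consecutive lagged phase points `c(pos, s*vel)`.
#' @param model an [ipc_state_space()] object.
#' @param dt sampling interval.
#' @return the predicted state, with attribute `"transition"` describing any
#'   threshold traversal.
#' @export
ipc_predict <- function(state, u, v, model, dt) {
  step <- function(st, d, active, lag) {
    mean <- as.numeric(d$Ad %*% st$mean)
    cov <- d$Ad %*% st$cov %*% t(d$Ad) + d$Qd
    if (active) {
      mean <- mean + as.numeric(d$Ataud %*% lag)
      cov <- cov + d$Ataud %*% st$cov %*% t(d$Ataud)
    }
    list(mean = mean, cov = (cov + t(cov)) / 2)
  }
  if (model$variant == "SDE") {
    out <- step(state, ipc_discretize(model, dt, active = FALSE), FALSE, NULL)
    attr(out, "transition") <- list(kind = "NONE")
    return(out)
  }
  if (model$variant == "SDDE") {
    out <- step(state, ipc_discretize(model, dt, active = TRUE), TRUE, v)
    attr(out, "transition") <- list(kind = "NONE")
    return(out)
  }
  tr <- cpp_transition(as.numeric(u), as.numeric(v), model$alpha, model$r, dt)
  if (tr$kind == "NONE") {
    out <- step(state, ipc_discretize(model, dt, active = tr$active_u),
                tr$active_u, v)
  } else if (tr$kind == "OFF") {
    st <- state
    if (tr$dt_minus > 0) {
      st <- step(st, ipc_discretize(model, tr$dt_minus, active = TRUE), TRUE, u)
    }
    if (tr$dt_plus > 0) {
      st <- step(st, ipc_discretize(model, tr$dt_plus, active = FALSE),
                 FALSE, NULL)
    }
    out <- st
  } else {
    st <- state
    if (tr$dt_minus > 0) {
      st <- step(st, ipc_discretize(model, tr$dt_minus, active = FALSE),
                 FALSE, NULL)
    }
    if (tr$dt_plus > 0) {
      st <- step(st, ipc_discretize(model, tr$dt_plus, active = TRUE), TRUE,
                 tr$crossing / c(1, model$s))
    }
    out <- st
  }
  attr(out, "transition") <- tr
  out
}

#' Measurement correction and likelihood increment
#'
#' Standard scalar Kalman update for the measurement `y = H x + mu + noise`:
#' innovation `e = y - (H mean + mu)`, innovation variance
#' `S = H cov H' + R`, gain `cov H' / S`, and -2 log-likelihood increment
#' `log(2 pi S) + e^2 / S`.
#'
#' @param state list with `mean` and `cov`.
#' @param y scalar observation.
#' @param model an [ipc_state_space()] object (uses `H` and `R`).
#' @param mu sway origin offset.
#' @return list with the corrected `state`, `innovation`, `S` and
#'   `loglik_increment` (the increment to -2 log L).
#' @export
ipc_correct <- function(state, y, model, mu = 0) {
  S <- as.numeric(model$H %*% state$cov %*% t(model$H) + model$R)
  if (!is.finite(S) || S <= 0) stop("non-positive innovation variance")
  e <- y - as.numeric(model$H %*% state$mean + mu)
  gain <- as.numeric(state$cov %*% t(model$H)) / S
  mean <- state$mean + gain * e
  cov <- (diag(2) - gain %*% model$H) %*% state$cov
  list(state = list(mean = mean, cov = (cov + t(cov)) / 2),
       innovation = e, S = S,
       loglik_increment = log(2 * pi * S) + e^2 / S)
}

# R reference filter: the same algorithm as the compiled path, assembled
# from the exported step functions. Used for structural cross-checks only.
ipc_filter_r <- function(y, dt, params, nuisance, constants, variant,
                         compat_lag = FALSE, p0 = 0) {
  model <- ipc_state_space(params, constants, variant)
  n <- length(y)
  state <- list(mean = c(nuisance$x0, nuisance$xdot0), cov = diag(p0, 2))
  buffer <- matrix(NA_real_, n, 2)
  m2ll <- 0
  innov <- numeric(n)
  lam <- params$tau / dt

  lag_q <- function(tq, imax) {
    if (tq <= 0) return(extrapolate_initial(nuisance, tq + params$tau, params$tau))
    lagged_state(buffer, imax, max(imax - 1 - tq / dt, 0), compat = compat_lag)
  }

  # conditioned on the first observation: its increment is not accumulated
  cr <- ipc_correct(state, y[1], model, nuisance$mu)
  state <- cr$state
  innov[1] <- cr$innovation
  buffer[1, ] <- state$mean

  for (i in seq_len(n - 1)) {
    t <- (i - 1) * dt
    u <- lag_q(t - params$tau, i)
    v <- lag_q(t + dt - params$tau, i)
    su <- c(u[1], model$s * u[2])
    sv <- c(v[1], model$s * v[2])
    state <- ipc_predict(state, su, if (model$variant == "SDDE") v else sv,
                         model, dt)
    cr <- ipc_correct(state, y[i + 1], model, nuisance$mu)
    state <- cr$state
    m2ll <- m2ll + cr$loglik_increment
    innov[i + 1] <- cr$innovation
    buffer[i + 1, ] <- state$mean
  }
  list(minus2LL = m2ll, innovations = innov)
}

#' -2 log-likelihood of a series under an IPC variant
#'
#' Runs the delayed switching Kalman filter over a uniformly sampled series
#' and returns the -2 log-likelihood by prediction-error decomposition,
#' conditioned on the first observation (with fitted initial values and zero
#' initial covariance the first innovation only anchors `x0 + mu` and would
#' otherwise degenerate as `eps` approaches 0). Lagged states before the
#' first observation come from the quadratic backward extrapolation, later
#' ones from interpolating the buffer of corrected means. The SDDE variant keeps the delayed term always
#' active (no switching); the SDE variant has no delay machinery at all.
#'
#' @param series an [ipc_trajectory()] of observations.
#' @param params [ipc_params()].
#' @param nuisance [ipc_nuisance()].
#' @param constants [ipc_constants()].
#' @param variant `"ISDDE"`, `"SDDE"` or `"SDE"`.
#' @param compat_lag use the paper-compatibility lag-interpolation sign.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @param p0 initial state covariance, as a scalar multiple of the identity.
#'   The default 0 reflects that the initial values are themselves fitted
#'   parameters; a diffuse override is available for sensitivity checks.
#' @param details if `TRUE`, also return innovations, innovation variances,
#'   filtered means and the count of threshold traversals.
#' @return the scalar -2 log-likelihood (`+Inf` for a divergent filter), or
#'   a list when `details = TRUE`.
#' @export
ipc_minus2_loglik <- function(series, params, nuisance = ipc_nuisance(),
                              constants = ipc_constants(), variant = "ISDDE",
                              compat_lag = FALSE,
                              engine = c("cpp", "r"), details = FALSE,
                              p0 = 0) {
  stopifnot(inherits(series, "ipc_trajectory"), inherits(params, "ipc_params"))
  engine <- match.arg(engine)
  variant <- match.arg(toupper(variant), VARIANTS)
  if (engine == "r") {
    out <- ipc_filter_r(series$values, series$dt, params, nuisance, constants,
                        variant, compat_lag, p0)
    return(if (details) out else out$minus2LL)
  }
  vc <- variant_code(variant)
  if (details) {
    cpp_filter_details(series$values, series$dt,
                       params$K, params$B, params$P, params$D, params$a,
                       params$r, params$tau, params$sigma, params$eps,
                       nuisance$x0, nuisance$xdot0, nuisance$xddot0,
                       nuisance$mu,
                       constants$mass, constants$com_height,
                       constants$gravity, constants$inertia,
                       vc, compat_lag, p0)
  } else {
    cpp_m2ll(series$values, series$dt,
             params$K, params$B, params$P, params$D, params$a,
             params$r, params$tau, params$sigma, params$eps,
             nuisance$x0, nuisance$xdot0, nuisance$xddot0, nuisance$mu,
             constants$mass, constants$com_height, constants$gravity,
             constants$inertia,
             vc, compat_lag, p0)
  }
}

#' Joint -2 log-likelihood over several trials
#'
#' Sums per-trial likelihoods under shared structural parameters with
#' trial-specific nuisance parameters, the objective used for joint
#' (multi-trial) estimation.
#'
#' @param trials list of [ipc_trajectory()] objects with identical sampling
#'   rates.
#' @param params shared [ipc_params()].
#' @param nuisances list of [ipc_nuisance()], one per trial.
#' @inheritParams ipc_minus2_loglik
#' @return scalar -2 log-likelihood.
#' @export
ipc_multi_minus2_loglik <- function(trials, params, nuisances,
                                    constants = ipc_constants(),
                                    variant = "ISDDE", compat_lag = FALSE) {
  stopifnot(length(trials) >= 1, length(nuisances) == length(trials))
  dts <- vapply(trials, function(tr) tr$dt, numeric(1))
  if (max(dts) - min(dts) > 1e-9 * dts[1]) {
    stop("all trials must share the same sampling rate")
  }
  sum(vapply(seq_along(trials), function(j) {
    ipc_minus2_loglik(trials[[j]], params, nuisances[[j]], constants,
                      variant, compat_lag)
  }, numeric(1)))
}
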