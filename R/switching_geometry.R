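# Phase-plane geometry of intermittent activation: the activation test, the
# classification of threshold traversals between consecutive lagged states,
# the interpolated crossing point, and the proportional time split.
#
# All coordinates are (position, s * velocity) with the seconds constant
# s = 1 s, so both axes are in radians.

#' Activation condition for a lagged phase point
#'
#' Active feedback requires the lagged state to lie strictly on the far side
#' of the switching line (`pos * (vel - alpha * pos) > 0`) and strictly
#' outside the insensitivity radius (`pos^2 + vel^2 > r^2`).
#'
#' @param pos,vel phase-plane coordinates (vectorized); `vel` is the
#'   s-scaled angular velocity.
#' @param alpha switching-line slope (see [alpha_from_a()]).
#' @param r insensitivity radius.
#' @return logical vector.
#' @export
is_active <- function(pos, vel, alpha, r) {
  stopifnot(length(pos) == length(vel))
  as.logical(cpp_is_active(as.numeric(pos), as.numeric(vel), alpha, r))
}

#' Classify the activation transition along a lagged segment
#'
#' Given consecutive lagged states `u` (earlier) and `v` (later) one step
#' apart, decides whether active feedback is switching `OFF` (u active, v
#' inactive), `ON` (the reverse), or `NONE`, and which geometric boundary the
#' segment crosses: the switching `LINE`, the insensitivity `CIRCLE`, or the
#' position `AXIS` (u = 0). For switching on, the roles of the endpoints are
#' traded before the off-side case logic is applied.
#'
#' @param u,v numeric length-2 phase points `c(pos, vel)`.
#' @param alpha switching-line slope.
#' @param r insensitivity radius.
#' @param dt interval between the two lagged states (used for the time
#'   split reported alongside).
#' @return a list with `kind` (`"ON"`, `"OFF"`, `"NONE"`), `case`, the
#'   interpolated `crossing` point, and `dt_minus`/`dt_plus`.
#' @export
classify_transition <- function(u, v, alpha, r, dt = 1) {
  stopifnot(length(u) == 2, length(v) == 2)
  cpp_transition(as.numeric(u), as.numeric(v), alpha, r, dt)
}

#' Interpolated threshold-crossing point
#'
#' Computes the point where the lagged segment `u -> v` meets the activation
#' boundary. On the `LINE` case the crossing lies exactly on
#' `vel = alpha * pos`; the `CIRCLE` case uses a first-order linearization of
#' the circle constraint around the destination point (it need not lie
#' exactly on the circle); the `AXIS` case crosses `pos = 0`. Degenerate
#' segments (zero length, or parallel to the switching line) fall back to the
#' shared point or the segment midpoint.
#'
#' @inheritParams classify_transition
#' @return numeric length-2 crossing point `c(pos, vel)`.
#' @export
crossing_point <- function(u, v, alpha, r) {
  tr <- classify_transition(u, v, alpha, r, dt = 1)
  if (identical(tr$kind, "NONE")) {
    stop("no activation transition between 'u' and 'v'")
  }
  tr$crossing
}

#' Proportional split of the step at a threshold crossing
#'
#' Splits the interval `dt` between the two lagged states in proportion to
#' the Euclidean distances from the endpoints to the crossing point,
#' clamping so that both pieces are non-negative and sum exactly to `dt`.
#'
#' @param u,v numeric length-2 phase points.
#' @param crossing crossing point from [crossing_point()].
#' @param dt interval length.
#' @return named numeric vector `c(dt_minus, dt_plus)`.
#' @export
split_interval <- function(u, v, crossing, dt) {
  stopifnot(length(u) == 2, length(v) == 2, length(crossing) == 2, dt >= 0)
  seg <- sqrt(sum((v - u)^2))
  if (seg == 0) return(c(dt_minus = 0, dt_plus = dt))
  dm <- sqrt(sum((crossing - u)^2)) / seg * dt
  dm <- min(max(dm, 0), dt)
  c(dt_minus = dm, dt_plus = dt - dm)
}
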