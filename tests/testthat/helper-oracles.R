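# Independent oracles used across the suite. These are deliberately written
# from textbook formulas, not from the package's own code paths.

# Standard (delay-free) Kalman filter -2 log-likelihood for
#   x_{t+1} = Ad x_t + N(0, Qd),  y_t = H x_t + mu + N(0, R)
# with fixed initial mean/covariance.
textbook_kf_m2ll <- function(y, Ad, Qd, H, R, mu, m0, P0) {
  m <- m0
  P <- P0
  out <- 0
  for (i in seq_along(y)) {
    if (i > 1) {
      m <- Ad %*% m
      P <- Ad %*% P %*% t(Ad) + Qd
    }
    S <- as.numeric(H %*% P %*% t(H) + R)
    e <- y[i] - as.numeric(H %*% m + mu)
    out <- out + log(2 * pi * S) + e^2 / S
    K <- P %*% t(H) / S
    m <- m + K * e
    P <- (diag(2) - K %*% H) %*% P
  }
  out
}

# Simpson-rule quadrature of the process-noise integral
#   Qd = int_0^dt expm(A s) Q expm(A s)' ds
# using Matrix::expm as the independent matrix exponential.
quadrature_Qd <- function(A, Q, dt, ns = 200) {
  xs <- seq(0, dt, length.out = ns + 1)
  w <- c(1, rep(c(4, 2), ns / 2 - 1), 4, 1) * dt / (3 * ns)
  acc <- matrix(0, 2, 2)
  for (k in seq_along(xs)) {
    E <- as.matrix(Matrix::expm(A * xs[k]))
    acc <- acc + w[k] * (E %*% Q %*% t(E))
  }
  acc
}

# dense sub-sampling of a lagged segment: endpoint activity and the first
# boundary crossing found by brute force
brute_transition <- function(u, v, alpha, r, n = 1e4) {
  tt <- seq(0, 1, length.out = n)
  px <- u[1] + tt * (v[1] - u[1])
  pv <- u[2] + tt * (v[2] - u[2])
  act <- (px * (pv - alpha * px) > 0) & (px^2 + pv^2 > r^2)
  flip <- which(diff(act) != 0)
  list(active_u = act[1], active_v = act[n],
       kind = if (act[1] == act[n]) "NONE" else if (act[1]) "OFF" else "ON",
       first_cross = if (length(flip)) c(px[flip[1]], pv[flip[1]]) else NULL)
}

# quick simulated observation set for fitting tests
make_noisy_trials <- function(preset, n_trials, duration, seed,
                              fine_dt = 1e-4, hz = 100) {
  p <- ipc_preset(preset)
  seeds <- seed_stream(seed, n_trials)
  lapply(seq_len(n_trials), function(j) {
    tr <- ipc_simulate(p, duration = duration, fine_dt = fine_dt,
                       seed = seeds[j], record_hz = hz)
    observe(tr, eps = p$eps, mu = 0)
  })
}
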