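# Structural parameters, state-space construction, and discretization.

test_that("alpha_from_a follows the tangent parameterization", {
  expect_equal(alpha_from_a(0), 0)
  expect_equal(alpha_from_a(0.25), 1)
  expect_equal(alpha_from_a(0.62), tan(0.62 * pi), tolerance = 1e-12)
  expect_lt(alpha_from_a(0.62), -2.5)  # steep negative slope past vertical
  expect_error(alpha_from_a(0.5), "vertical")
  expect_error(alpha_from_a(1.2), "0, 1")
  # monotone increasing on each branch
  lo <- alpha_from_a(seq(0, 0.49, by = 0.07))
  hi <- alpha_from_a(seq(0.51, 1, by = 0.07))
  expect_true(all(diff(lo) > 0))
  expect_true(all(diff(hi) > 0))
})

test_that("state-space matrices carry the pendulum ratios", {
  cons <- ipc_constants(mass = 70, com_height = 0.9)
  p <- ipc_params(K = 0.8, B = 4, P = 0.25, D = 10, a = 0.62, r = 0.4,
                  tau = 0.2, sigma = 0.2, eps = 1e-4)
  m <- ipc_state_space(p, cons, "ISDDE")
  expect_equal(m$A[1, ], c(0, 1))
  # with I = m h^2, the gravitational stiffness reduces to g (1 - K) / h
  expect_equal(m$A[2, 1], 9.81 * 0.2 / 0.9, tolerance = 1e-12)
  expect_equal(m$A[2, 2], -4 / (70 * 0.9^2))
  expect_equal(m$Atau[1, ], c(0, 0))
  expect_equal(m$Atau[2, 1], -9.81 * 0.25 / 0.9, tolerance = 1e-12)
  expect_equal(m$Q, diag(c(0, 0.04)))
  expect_equal(as.numeric(m$H), c(1, 0))
  expect_equal(as.numeric(m$R), 1e-4)

  # stiffness exactly cancelling gravity
  m1 <- ipc_state_space(ipc_params(K = 1, B = 0, a = 0.2), cons, "ISDDE")
  expect_equal(m1$A, matrix(c(0, 0, 1, 0), 2, 2))
  # SDE variant zeroes the delayed block
  m2 <- ipc_state_space(p, cons, "SDE")
  expect_equal(m2$Atau, matrix(0, 2, 2))
  # unit invariance: only ratios enter
  cons2 <- ipc_constants(mass = 70000, com_height = 0.9,
                         inertia = 70000 * 0.9^2)
  m3 <- ipc_state_space(p, cons2, "ISDDE")
  expect_equal(m3$A[2, 1], m$A[2, 1])
  expect_equal(m3$Atau[2, 1], m$Atau[2, 1])
})

test_that("constants are validated", {
  expect_error(ipc_constants(mass = -1), "positive")
  expect_error(ipc_params(K = 0.8, B = 4, a = 2), "0, 1")
  expect_error(ipc_params(K = 0.8, B = 4, sigma = -1), "sigma")
})

test_that("discretization matches the independent matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  p <- ipc_params(K = 0.8, B = 4, P = 0.25, D = 10, a = 0.62, r = 0.4,
                  tau = 0.2, sigma = 0.7)
  mod <- ipc_state_space(p, ipc_constants(), "ISDDE")
  for (dt in c(0.001, 0.01, 0.1)) {
    d <- ipc_discretize(mod, dt)
    expect_equal(d$Ad, as.matrix(Matrix::expm(mod$A * dt)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(d$Qd, quadrature_Qd(mod$A, mod$Q, dt),
                 tolerance = 1e-7, ignore_attr = TRUE)
    # classical inversion-based formula on this well-conditioned A
    ref <- solve(mod$A) %*% (as.matrix(Matrix::expm(mod$A * dt)) - diag(2)) %*%
      mod$Atau
    expect_equal(d$Ataud, ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("discretization limits and degenerate cases", {
  mod <- ipc_state_space(ipc_params(K = 0.9, B = 2, P = 0.1, D = 5, a = 0.3,
                                    sigma = 0.5), ipc_constants(), "ISDDE")
  # dt -> 0: Ad -> I, Qd -> 0
  d0 <- ipc_discretize(mod, 1e-10)
  expect_equal(d0$Ad, diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(d0$Qd)), 1e-9)
  # A strictly zero: the integrand is constant, Qd = Q dt exactly
  dz0 <- ipcfit:::cpp_kalman_integrate(matrix(0, 2, 2), matrix(0, 2, 2),
                                       diag(c(0, 0.25)), 0.02)
  expect_equal(dz0$Qd, diag(c(0, 0.25)) * 0.02, tolerance = 1e-14)
  # K = 1, B = 0 (nilpotent A): exact closed form of the noise integral
  modz <- ipc_state_space(ipc_params(K = 1, B = 0, sigma = 0.5),
                          ipc_constants(), "SDE")
  dz <- ipc_discretize(modz, 0.02)
  s2 <- 0.25; dt <- 0.02
  expect_equal(dz$Qd,
               s2 * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # K = 1 (singular A) is legal for the delayed model too
  mods <- ipc_state_space(ipc_params(K = 1, B = 0, P = 0.2, D = 5, a = 0.3,
                                     sigma = 0.1), ipc_constants(), "ISDDE")
  ds <- ipc_discretize(mods, 0.01)
  expect_true(all(is.finite(ds$Ataud)))
  # Atau = 0 stays zero, inactive flag zeroes it as well
  modsde <- ipc_state_space(ipc_params(K = 0.8, B = 4), ipc_constants(), "SDE")
  expect_equal(ipc_discretize(modsde, 0.01)$Ataud, matrix(0, 2, 2))
  expect_equal(ipc_discretize(mod, 0.01, active = FALSE)$Ataud,
               matrix(0, 2, 2))
  expect_error(ipc_discretize(mod, -1), "positive")
})

test_that("discretization satisfies the semigroup property and keeps Qd PSD", {
  set.seed(42)
  for (i in 1:20) {
    p <- ipc_params(K = runif(1, 0, 1.2), B = runif(1, -50, 200),
                    P = runif(1, 0, 2), D = runif(1, -100, 100), a = 0.3,
                    sigma = runif(1, 0, 3))
    mod <- ipc_state_space(p, ipc_constants(), "ISDDE")
    dt <- runif(1, 1e-3, 0.05)
    d1 <- ipc_discretize(mod, dt)
    d2 <- ipc_discretize(mod, 2 * dt)
    expect_equal(d1$Ad %*% d1$Ad, d2$Ad, tolerance = 1e-11,
                 ignore_attr = TRUE)
    ev <- eigen(d1$Qd, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-14 * max(abs(ev), 1)))
  }
})
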