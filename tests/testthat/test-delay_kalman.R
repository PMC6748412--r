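# Delayed switching Kalman filter: lag interpolation, backward
# extrapolation, prediction/correction steps, oracle equivalences.

test_that("lagged_state interpolates the buffer (default and compat signs)", {
  buf <- cbind(0:9, (0:9) * 10)  # position 0..9, velocity 0..90
  expect_equal(lagged_state(buf, i = 10, lam = 3), c(6, 60))
  # spec midpoint: lam = 2.5 between rows i-2 and i-3
  buf2 <- cbind(c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0), 0)
  b <- rbind(c(0, 0))
  buf3 <- cbind(rep(0, 10), rep(0, 10))
  buf3[8, 1] <- 1.0  # x_{i-2} for i = 10
  buf3[7, 1] <- 0.0  # x_{i-3}
  expect_equal(lagged_state(buf3, 10, 2.5)[1], 0.5)
  expect_equal(lagged_state(buf3, 10, 2.5, compat = TRUE)[1], 1.5)
  # tau = 0: most recent entry
  expect_equal(lagged_state(buf, 10, 0), c(9, 90))
  expect_error(lagged_state(buf[0, , drop = FALSE], 1, 1), "empty")
})

test_that("extrapolate_initial is the printed quadratic (no 1/2 factor)", {
  nu <- ipc_nuisance(x0 = 1, xdot0 = 2, xddot0 = 10)
  expect_equal(extrapolate_initial(nu, t = 0.2, tau = 0.2), c(1, 2))
  expect_equal(extrapolate_initial(ipc_nuisance(x0 = 1, xdot0 = 2), 0, 0.2),
               c(1 - 0.4, 2))
  expect_equal(extrapolate_initial(nu, t = 0, tau = 0.2), c(1.0, -2.0))
})

test_that("correction is the scalar conjugate Gaussian update", {
  mod <- ipc_state_space(ipc_params(K = 0.8, B = 4, eps = 0.25),
                         ipc_constants(), "SDE")
  # zero covariance: prior believed exactly, increment from R alone
  st <- list(mean = c(1, 0), cov = matrix(0, 2, 2))
  cr <- ipc_correct(st, y = 1.4, mod, mu = 0.1)
  expect_equal(cr$state$mean, c(1, 0))
  expect_equal(cr$loglik_increment, log(2 * pi * 0.25) + 0.3^2 / 0.25)
  # huge R: posterior equals prior (zero gain limit)
  modR <- ipc_state_space(ipc_params(K = 0.8, B = 4, eps = 1e12),
                          ipc_constants(), "SDE")
  st2 <- list(mean = c(1, 0), cov = diag(c(0.5, 0.5)))
  cr2 <- ipc_correct(st2, y = 100, modR)
  expect_equal(cr2$state$mean, c(1, 0), tolerance = 1e-8)
  # conjugate posterior oracle in one dimension:
  # prior N(m, v), likelihood N(y; x, R) -> posterior mean (m/v + y/R)/(1/v + 1/R)
  st3 <- list(mean = c(2, 0), cov = diag(c(0.3, 0)))
  cr3 <- ipc_correct(st3, y = 3, mod)
  expect_equal(cr3$state$mean[1],
               (2 / 0.3 + 3 / 0.25) / (1 / 0.3 + 1 / 0.25),
               tolerance = 1e-12)
  expect_equal(cr3$state$cov[1, 1], 1 / (1 / 0.3 + 1 / 0.25),
               tolerance = 1e-12)
})

test_that("prediction reduces to the textbook step without delayed terms", {
  mod <- ipc_state_space(ipc_params(K = 0.8, B = 4, sigma = 0.3),
                         ipc_constants(), "SDE")
  d <- ipc_discretize(mod, 0.01, active = FALSE)
  st <- list(mean = c(0.3, -0.1), cov = diag(c(0.2, 0.4)))
  pr <- ipc_predict(st, c(0, 0), c(0, 0), mod, 0.01)
  expect_equal(pr$mean, as.numeric(d$Ad %*% st$mean))
  expect_equal(pr$cov, d$Ad %*% st$cov %*% t(d$Ad) + d$Qd,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a traversal with the crossing at an endpoint matches a single step", {
  p <- ipc_params(K = 0.8, B = 4, P = 0.25, D = 10, a = 0.62, r = 0.4,
                  tau = 0.2, sigma = 0.2)
  mod <- ipc_state_space(p, ipc_constants(), "ISDDE")
  st <- list(mean = c(0.5, 0.1), cov = diag(c(0.01, 0.01)))
  # u active, v exactly on the radius boundary (inactive, strict >):
  # crossing ~ v so dt_minus ~ dt and the two-step path approaches the
  # single fully-active step
  u <- c(0.5, 0.4)
  v <- c(0.4 - 1e-9, 1e-9)
  two <- ipc_predict(st, u, v, mod, 0.01)
  dact <- ipc_discretize(mod, 0.01, active = TRUE)
  one_mean <- as.numeric(dact$Ad %*% st$mean + dact$Ataud %*% u)
  expect_equal(two$mean, one_mean, tolerance = 1e-4)
})

test_that("SDE variant equals an independent textbook Kalman filter", {
  p <- ipc_params(K = 0.85, B = 12, sigma = 0.4, eps = 1e-3)
  cons <- ipc_constants()
  set.seed(9)
  tr <- ipc_simulate(p, cons, duration = 5, fine_dt = 1e-4, x0 = 0.2,
                     xdot0 = -0.1, record_hz = 100)
  y <- observe(tr, eps = 1e-3, mu = 0.05, seed = 10)
  mod <- ipc_state_space(p, cons, "SDE")
  d <- ipc_discretize(mod, 0.01, active = FALSE)
  ref <- textbook_kf_m2ll(y$values, d$Ad, d$Qd, mod$H, mod$R, mu = 0.05,
                          m0 = c(0.2, -0.1), P0 = matrix(0, 2, 2))
  # the package likelihood conditions on the first observation (see the
  # vignette); remove the oracle's first increment accordingly
  ref <- ref - (log(2 * pi * as.numeric(mod$R)) +
                  (y$values[1] - 0.2 - 0.05)^2 / as.numeric(mod$R))
  got <- ipc_minus2_loglik(y, p, ipc_nuisance(x0 = 0.2, xdot0 = -0.1,
                                              mu = 0.05),
                           cons, variant = "SDE")
  expect_equal(got, ref, tolerance = 1e-8)
})

test_that("compiled and reference filters agree on a delayed switching series", {
  p <- ipc_params(K = 0.8, B = 4, P = 0.25, D = 10, a = 0.62, r = 0.1,
                  tau = 0.15, sigma = 0.3, eps = 1e-4)
  cons <- ipc_constants()
  set.seed(21)
  tr <- ipc_simulate(p, cons, duration = 4, fine_dt = 1e-4, record_hz = 50)
  y <- observe(tr, eps = 1e-4, seed = 22)
  nu <- ipc_nuisance()
  for (variant in c("ISDDE", "SDDE", "SDE")) {
    a <- ipc_minus2_loglik(y, p, nu, cons, variant, engine = "cpp")
    b <- ipc_minus2_loglik(y, p, nu, cons, variant, engine = "r")
    expect_equal(a, b, tolerance = 1e-8, label = variant)
  }
  # compat lag mode agrees between engines as well
  a <- ipc_minus2_loglik(y, p, nu, cons, "ISDDE", compat_lag = TRUE)
  b <- ipc_minus2_loglik(y, p, nu, cons, "ISDDE", compat_lag = TRUE,
                         engine = "r")
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("likelihood responds continuously across a traversal boundary", {
  # nudging tau so a lagged segment slides its crossing out of the interval
  # must not produce a jump beyond the one-step contribution
  p <- ipc_params(K = 0.8, B = 4, P = 0.25, D = 10, a = 0.62, r = 0.3,
                  tau = 0.2, sigma = 0.3, eps = 1e-4)
  cons <- ipc_constants()
  set.seed(33)
  tr <- ipc_simulate(p, cons, duration = 6, fine_dt = 1e-4, record_hz = 100)
  y <- observe(tr, eps = 1e-4, seed = 34)
  taus <- seq(0.195, 0.205, by = 0.0005)
  vals <- vapply(taus, function(tv) {
    pp <- p; pp$tau <- tv
    ipc_minus2_loglik(y, pp, ipc_nuisance(), cons)
  }, numeric(1))
  expect_true(all(is.finite(vals)))
  expect_lt(max(abs(diff(vals))), 0.05 * diff(range(vals)) + 5)
})

test_that("filter keeps covariances symmetric PSD and counts traversals", {
  p <- ipc_params(K = 0.8, B = 4, P = 0.25, D = 10, a = 0.62, r = 0.2,
                  tau = 0.2, sigma = 0.5, eps = 1e-4)
  cons <- ipc_constants()
  set.seed(41)
  tr <- ipc_simulate(p, cons, duration = 10, fine_dt = 1e-4, record_hz = 100)
  y <- observe(tr, eps = 1e-4, seed = 42)
  det <- ipc_minus2_loglik(y, p, ipc_nuisance(), cons, details = TRUE)
  expect_true(det$ok)
  expect_length(det$innovations, length(y$values))
  expect_true(all(det$S > 0))
  expect_gt(det$n_traversals, 0)
})

test_that("multi-trial likelihood is additive with shared parameters", {
  p <- ipc_params(K = 0.8, B = 4, P = 0.25, D = 10, a = 0.62, r = 0.2,
                  tau = 0.2, sigma = 0.3, eps = 1e-4)
  cons <- ipc_constants()
  trials <- lapply(1:3, function(j) {
    tr <- ipc_simulate(p, cons, duration = 3, fine_dt = 1e-4, seed = j,
                       record_hz = 100)
    observe(tr, eps = 1e-4, seed = 10 + j)
  })
  nus <- replicate(3, ipc_nuisance(), simplify = FALSE)
  single <- vapply(1:3, function(j) {
    ipc_minus2_loglik(trials[[j]], p, nus[[j]], cons)
  }, numeric(1))
  expect_equal(ipc_multi_minus2_loglik(trials, p, nus, cons), sum(single))
  expect_equal(ipc_multi_minus2_loglik(trials[c(1, 1)], p, nus[c(1, 1)], cons),
               2 * single[1])
  bad <- trials
  bad[[2]]$dt <- 0.02
  expect_error(ipc_multi_minus2_loglik(bad, p, nus, cons), "sampling rate")
})

test_that("the objective is lowest near the generating parameters", {
  p <- ipc_params(K = 0.8, B = 4, P = 0.25, D = 10, a = 0.62, r = 0.2,
                  tau = 0.2, sigma = 0.3, eps = 1e-4)
  cons <- ipc_constants()
  set.seed(55)
  wins <- 0
  for (i in 1:40) {
    tr <- ipc_simulate(p, cons, duration = 5, fine_dt = 1e-4,
                       seed = 1000 + i, record_hz = 100)
    y <- observe(tr, eps = 1e-4, seed = 2000 + i)
    at_truth <- ipc_minus2_loglik(y, p, ipc_nuisance(), cons)
    pp <- p
    pp$K <- p$K * runif(1, 0.7, 1.3)
    pp$sigma <- p$sigma * runif(1, 0.5, 2)
    pp$tau <- min(max(p$tau * runif(1, 0.8, 1.2), 0), 0.25)
    perturbed <- ipc_minus2_loglik(y, pp, ipc_nuisance(), cons)
    wins <- wins + (at_truth < perturbed)
  }
  expect_gte(wins / 40, 0.95)
})
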