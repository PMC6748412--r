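# Activation conditions, threshold-crossing classification and
# interpolation in the (angle, scaled-velocity) phase plane.

test_that("is_active applies strict line and radius thresholds", {
  expect_false(is_active(0, 0, alpha = 1, r = 0.1))          # inside radius
  expect_true(is_active(0.2, 0.3, alpha = 1, r = 0.1))       # 0.2*0.1 > 0
  expect_false(is_active(0.3, 0.25, alpha = 1, r = 0.1))     # wrong side
  # boundary: exactly on the line or circle is inactive (strict >)
  expect_false(is_active(0.2, 0.2, alpha = 1, r = 0.1))
  expect_false(is_active(0.1, 0, alpha = -1, r = 0.1))
  # point symmetry of the geometry
  set.seed(7)
  for (i in 1:50) {
    pt <- rnorm(2)
    al <- rnorm(1)
    expect_identical(is_active(pt[1], pt[2], al, 0.3),
                     is_active(-pt[1], -pt[2], al, 0.3))
  }
})

test_that("transitions are classified and crossings interpolated per case", {
  # OFF through the switching line
  tr <- classify_transition(c(0.2, 0.3), c(0.3, 0.25), alpha = 1, r = 0.1,
                            dt = 0.01)
  expect_equal(tr$kind, "OFF")
  expect_equal(tr$case, "LINE")
  expect_equal(tr$crossing, c(0.26667, 0.26667), tolerance = 1e-4)
  # the LINE crossing lies exactly on vel = alpha * pos
  expect_equal(tr$crossing[2], 1 * tr$crossing[1], tolerance = 1e-12)
  expect_equal(tr$dt_minus, 0.0066667, tolerance = 1e-4)
  expect_equal(tr$dt_minus + tr$dt_plus, 0.01)

  # OFF into the insensitivity circle, horizontal segment (m = 0)
  tr2 <- classify_transition(c(0.2, 0.05), c(0.05, 0.05), alpha = -1, r = 0.1,
                             dt = 0.01)
  expect_equal(tr2$kind, "OFF")
  expect_equal(tr2$case, "CIRCLE")
  expect_equal(tr2$crossing, c(0.1, 0.05), tolerance = 1e-12)

  # AXIS crossing with m = 0: velocity carried over (feedback switching on
  # as the lagged state passes u = 0 into the active quadrant)
  tr3 <- classify_transition(c(0.1, -0.2), c(-0.1, -0.2), alpha = 1, r = 0.05,
                             dt = 0.01)
  expect_equal(tr3$kind, "ON")
  expect_equal(tr3$case, "AXIS")
  expect_equal(tr3$crossing, c(0, -0.2), tolerance = 1e-12)

  # both endpoints active -> no transition
  tr4 <- classify_transition(c(0.2, 0.3), c(0.25, 0.35), alpha = 1, r = 0.1)
  expect_equal(tr4$kind, "NONE")

  # switching ON trades endpoint roles but uses the same formulas
  tr5 <- classify_transition(c(0.3, 0.25), c(0.2, 0.3), alpha = 1, r = 0.1,
                             dt = 0.01)
  expect_equal(tr5$kind, "ON")
  expect_equal(tr5$case, "LINE")
  expect_equal(tr5$crossing, c(0.26667, 0.26667), tolerance = 1e-4)
})

test_that("split_interval is a clamped distance-proportional split", {
  u <- c(0.2, 0.3); v <- c(0.3, 0.25)
  expect_equal(split_interval(u, v, (u + v) / 2, 0.01),
               c(dt_minus = 0.005, dt_plus = 0.005))
  s <- split_interval(u, v, c(0.26667, 0.26667), 0.01)
  expect_equal(unname(s[1]), 0.0066667, tolerance = 1e-4)
  expect_equal(unname(sum(s)), 0.01)
  expect_equal(split_interval(u, v, u, 0.01),
               c(dt_minus = 0, dt_plus = 0.01))
  expect_equal(split_interval(u, u, u, 0.01),
               c(dt_minus = 0, dt_plus = 0.01))
  # a crossing beyond v (linearized circle case) is clamped
  s2 <- split_interval(u, v, v + 10 * (v - u), 0.01)
  expect_equal(unname(s2[1]), 0.01)
})

test_that("classification agrees with dense segment sub-sampling", {
  set.seed(11)
  n_ok <- 0; n <- 0
  for (i in 1:300) {
    u <- rnorm(2, sd = 0.5); v <- u + rnorm(2, sd = 0.3)
    alpha <- tan(runif(1, 0.05, 0.95) * pi)
    r <- runif(1, 0.05, 0.5)
    bf <- brute_transition(u, v, alpha, r)
    tr <- classify_transition(u, v, alpha, r, dt = 1)
    # skip degenerate draws where an endpoint sits within sampling
    # resolution of a boundary
    edge <- min(abs(c(u[1] * (u[2] - alpha * u[1]),
                      v[1] * (v[2] - alpha * v[1]),
                      u[1]^2 + u[2]^2 - r^2, v[1]^2 + v[2]^2 - r^2)))
    if (edge < 1e-4) next
    n <- n + 1
    ok <- identical(tr$kind, bf$kind)
    if (ok && tr$kind != "NONE" && !is.null(bf$first_cross) &&
        tr$case != "CIRCLE") {
      # interpolated crossing close to the brute-force first crossing
      ok <- sqrt(sum((tr$crossing - bf$first_cross)^2)) <
        0.02 * (1 + sqrt(sum((v - u)^2)))
    }
    n_ok <- n_ok + ok
  }
  expect_gt(n, 200)
  expect_gte(n_ok / n, 0.99)
})

test_that("crossings are convex combinations after clamping", {
  set.seed(13)
  for (i in 1:200) {
    u <- rnorm(2, sd = 0.4); v <- u + rnorm(2, sd = 0.3)
    alpha <- tan(runif(1, 0.05, 0.95) * pi)
    r <- runif(1, 0.05, 0.4)
    tr <- classify_transition(u, v, alpha, r, dt = 0.01)
    if (tr$kind == "NONE") next
    s <- split_interval(u, v, tr$crossing, 0.01)
    expect_gte(unname(s[1]), 0)
    expect_gte(unname(s[2]), 0)
    expect_equal(unname(sum(s)), 0.01, tolerance = 1e-15)
  }
})
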