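test_that("derivative fields match direct substitution", {
  expect_equal(linear_derivative(c(0, 0), c(0, 0)), c(0, 0))
  expect_equal(linear_derivative(c(1, 0), c(0, 0)), c(-4, 20))
  expect_equal(linear_derivative(c(0, 0), c(0.02, 0)), c(1, 0))
  expect_equal(vdp_derivative(c(0, 0), c(0, 0)), c(0, 0))
  expect_equal(vdp_derivative(c(1, 0), c(0, 0)), c(0, -8))
  expect_equal(lorenz_derivative(c(0, 0, -28)), c(0, 0, 0))
  expect_equal(lorenz_derivative(c(1, 1, 0)), c(0, -1, 1 - 224 / 3))
  # odd input non-linearity: g(0.1) = 10 * (1 - 0.25) = 7.5
  expect_equal(ff_nonlinear_derivative(c(0, 0), c(0.1, 0))[1], 7.5)
  expect_equal(ff_nonlinear_derivative(c(0, 0), c(-0.1, 0))[1], -7.5)
  expect_equal(ff_nonlinear_derivative(c(0.3, -0.2), c(0, 0)),
               linear_derivative(c(0.3, -0.2), c(0, 0)))
})

test_that("torque clipping: piecewise values, continuity, oddness", {
  expect_equal(torque_clip(c(0, 0), c(3, 3)), c(0, 0))
  expect_equal(torque_clip(c(1, 1), c(3 * pi / 4, 5 * pi / 8)), c(0, 0.5))
  expect_equal(torque_clip(c(1, -2), c(0.2, -0.3)), c(1, -2))
  # continuity in theta around the corners
  th <- seq(pi / 2 - 0.05, 3 * pi / 4 + 0.05, length.out = 400)
  tq <- vapply(th, function(t) torque_clip(c(1, 0), c(t, 0))[1], numeric(1))
  expect_lt(max(abs(diff(tq))), 0.01)
  # odd under (u, theta) -> (-u, -theta)
  for (th1 in c(0.3, 1.8, 2.5)) {
    expect_equal(torque_clip(c(-1, 0), c(-th1, 0)),
                 -torque_clip(c(1, 0), c(th1, 0)))
  }
})

test_that("arm dynamics: hanging equilibrium and energy consistency", {
  p <- arm_params()
  d0 <- arm_derivative(c(0, 0), c(0, 0), c(0, 0), p)
  expect_equal(d0$dtheta, c(0, 0))
  expect_equal(d0$domega, c(0, 0))
  # undamped, unforced: mechanical energy drift shrinks linearly with dt
  p0 <- arm_params(b11 = 1e-12, b12 = 1e-12, b21 = 1e-12, b22 = 1e-12)
  energy <- function(th, om) {
    d1 <- p0$I1 + p0$I2 + p0$m2 * p0$l1^2
    d2 <- p0$m2 * p0$l1 * p0$s2
    d3 <- p0$I2
    M <- matrix(c(d1 + 2 * d2 * cos(th[2]) + p0$m1 * p0$s1^2 + p0$m2 * p0$s2^2,
                  d3 + d2 * cos(th[2]) + p0$m2 * p0$s2^2,
                  d3 + d2 * cos(th[2]) + p0$m2 * p0$s2^2,
                  d3 + p0$m2 * p0$s2^2), 2, 2)
    ke <- 0.5 * drop(om %*% M %*% om)
    pe <- -p0$g * ((p0$m1 * p0$s1 + p0$m2 * p0$l1) * cos(th[1]) +
                     p0$m2 * p0$s2 * cos(th[1] + th[2]))
    ke + pe
  }
  drift <- vapply(c(1e-4, 1e-5), function(dt) {
    x <- c(0.6, -0.4, 0, 0)
    e0 <- energy(x[1:2], x[3:4])
    for (i in seq_len(round(1 / dt))) {
      d <- arm_derivative(x[1:2], x[3:4], c(0, 0), p0)
      x <- x + dt * c(d$dtheta, d$domega)
    }
    abs(energy(x[1:2], x[3:4]) - e0)
  }, numeric(1))
  expect_equal(drift[1] / drift[2], 10, tolerance = 0.3)
})

test_that("integrator preserves equilibria exactly", {
  dt <- 1e-3
  u2 <- matrix(0, 100, 2)
  for (sys in c("linear", "vanderpol", "ff_nonlinear")) {
    sp <- reference_spec(sys)
    x <- integrate_reference(sp, u2, dt)
    expect_true(all(x == 0))
  }
  sp <- reference_spec("lorenz", x0 = c(0, 0, -28))
  x <- integrate_reference(sp, matrix(0, 100, 3), dt)
  expect_true(all(x[, 1:2] == 0) && all(x[, 3] == -28))
  sp <- reference_spec("arm")
  x <- integrate_reference(sp, matrix(0, 100, 2), dt)
  expect_true(all(x == 0))
})

test_that("Euler trajectories agree with an adaptive-step oracle", {
  skip_if_not_installed("deSolve")
  dt <- 1e-3
  set.seed(40)
  u <- babbling_input(2, dt, 2, 0.03, 0.06, pedestal_period = 1)
  sp <- reference_spec("linear")
  x <- integrate_reference(sp, u, dt)
  f <- function(t, y, p)
    list(linear_derivative(y, u[pmin(floor(t / dt) + 1, nrow(u)), ]))
  o <- deSolve::ode(c(0, 0), seq(0, 2, by = dt), f, NULL,
                    rtol = 1e-8, atol = 1e-10)
  ref <- o[-1, 2:3]
  scale <- sqrt(mean(ref^2))
  expect_lt(sqrt(mean((x - ref)^2)) / scale, 0.02)
})

test_that("arm integration applies the network-unit scalings", {
  sp <- reference_spec("arm")
  u <- matrix(rep(c(0.5, -0.2), each = 500), 500, 2)
  x <- integrate_reference(sp, u, 1e-3, n_substeps = 1)
  # undo the scalings and re-integrate by hand in raw units
  xr <- c(0, 0, 0, 0)
  for (t in 1:500) {
    d <- arm_derivative(xr[1:2], xr[3:4], u[t, ], sp$params)
    xr <- xr + 1e-3 * c(d$dtheta, d$domega)
  }
  expect_equal(x[500, ], xr * c(1 / 2.5, 1 / 2.5, 0.05, 0.05),
               tolerance = 1e-6)
  expect_true(max(abs(x[, 1])) > 0)    # the arm actually moves
})

test_that("non-finite blow-up is reported with a time stamp", {
  sp <- reference_spec("vanderpol")
  u <- matrix(1e6, 200, 2)
  expect_error(integrate_reference(sp, u, 1e-3), "non-finite")
})
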