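test_that("silent network: zero weights and no feedback leave the output at zero", {
  # the decoded output at rest is the auto-encoder's reconstruction of
  # the origin: zero up to spiking fluctuations, regardless of the input
  net <- tiny_network(n_cmd = 200, n_rec = 200)
  set.seed(50)
  u <- babbling_input(1, 1e-3, 2, 0.05, 0.1, pedestal_period = 0.5)
  xr <- matrix(0.3, nrow(u), 2)
  ph <- run_phase(net, u, xr, feedback_on = FALSE, plasticity_on = FALSE)
  expect_lt(mean(abs(ph$xhat)), 0.1 * mean(abs(xr)))
  expect_equal(ph$eps, xr, tolerance = 0.1)
  # a population held below threshold is exactly silent
  silent <- net
  silent$rec$biases <- rep(-0.5, 200)
  ph0 <- run_phase(silent, u, xr, feedback_on = FALSE, plasticity_on = FALSE)
  expect_true(all(ph0$xhat == 0))
})

test_that("zero learning rate leaves weights bit-identical", {
  net <- tiny_network()
  set.seed(51)
  u <- babbling_input(0.5, 1e-3, 2, 0.05, 0.1, pedestal_period = 0.5)
  xr <- matrix(0.1, nrow(u), 2)
  ph <- run_phase(net, u, xr, feedback_on = TRUE, plasticity_on = TRUE,
                  eta = 0)
  expect_identical(ph$net$w_ff, net$w_ff)
  expect_identical(ph$net$w_rec, net$w_rec)
})

test_that("current assembly follows the architecture", {
  net <- tiny_network()
  u <- c(0.05, -0.03)
  expect_equal(command_currents(net, u),
               drop(scaled_encoders(net$cmd) %*% u) + net$cmd$biases)
  # linearity in the command around the bias
  b <- net$cmd$biases
  expect_equal(command_currents(net, c(0, 0)), b)
  expect_equal(command_currents(net, c(0.1, 0.2)) - b,
               (command_currents(net, c(0.1, 0)) - b) +
                 (command_currents(net, c(0, 0.2)) - b))
  # zero weights: recurrent current is bias plus scaled projected error
  eps <- c(0.2, -0.1)
  n <- net$rec$n_neurons
  J <- recurrent_currents(net, numeric(net$cmd$n_neurons), numeric(n), eps)
  expect_equal(J - net$rec$biases, net$k * drop(net$fb_encoders %*% eps))
  Joff <- recurrent_currents(net, numeric(net$cmd$n_neurons), numeric(n),
                             eps, feedback_on = FALSE)
  expect_equal(Joff, net$rec$biases)
})

test_that("FOLLOW increments have the stated product and rank-1 form", {
  net <- tiny_network(n_cmd = 3, n_rec = 4)
  le <- c(0.5, -0.2, 0, 1)
  ctr <- c(0.2, 0.1, 0.3)
  rtr <- c(1, 2, 3, 4)
  inc <- follow_update(net, le, ctr, rtr, eta = 2e-4, dt = 1e-3)
  expect_equal(inc$d_ff[1, 1], 2e-4 * 0.5 * 0.2 * 1e-3)  # = 2e-8
  expect_equal(inc$d_ff, 2e-4 * 1e-3 * outer(le, ctr))
  expect_equal(inc$d_rec, 2e-4 * 1e-3 * outer(le, rtr))
  # rows share the postsynaptic factor exactly (rank 1)
  expect_equal(qr(inc$d_rec)$rank, 1)
  # zero error history gives zero increments
  inc0 <- follow_update(net, numeric(4), ctr, rtr, 2e-4, 1e-3)
  expect_true(all(inc0$d_ff == 0) && all(inc0$d_rec == 0))
})

test_that("compiled and plain-R engines agree step for step", {
  net <- tiny_network(n_cmd = 25, n_rec = 30)
  set.seed(52)
  u <- babbling_input(1.5, 1e-3, 2, 0.05, 0.1, pedestal_period = 0.5)
  sp <- reference_spec("linear")
  xr <- integrate_reference(sp, u, 1e-3)
  # without plasticity the two formulations are mathematically identical
  a <- run_phase(net, u, xr, feedback_on = TRUE, plasticity_on = FALSE,
                 engine = "cpp", record_every = 1L)
  b <- run_phase(net, u, xr, feedback_on = TRUE, plasticity_on = FALSE,
                 engine = "r", record_every = 1L)
  expect_equal(a$xhat, b$xhat, tolerance = 1e-12)
  expect_equal(a$eps, b$eps, tolerance = 1e-12)
  expect_equal(a$count_rec, b$count_rec)
  # with plasticity the compiled engine freezes each spike's contribution
  # at the spike-time weights; discrete spike timing amplifies that tiny
  # difference, so agreement is statistical, not per-step
  ap <- run_phase(net, u, xr, plasticity_on = TRUE, eta = 2e-4,
                  update_every = 1L, engine = "cpp", record_every = 1L)
  bp <- run_phase(net, u, xr, plasticity_on = TRUE, eta = 2e-4,
                  update_every = 1L, engine = "r", record_every = 1L)
  relw <- sqrt(sum((ap$net$w_rec - bp$net$w_rec)^2)) /
    sqrt(sum(bp$net$w_rec^2))
  expect_lt(relw, 0.2)
  expect_equal(mean(ap$eps^2), mean(bp$eps^2), tolerance = 0.3)
})

test_that("blocked weight application is equivalent to the online rule", {
  net <- tiny_network(n_cmd = 25, n_rec = 30)
  set.seed(53)
  u <- babbling_input(2, 1e-3, 2, 0.05, 0.1, pedestal_period = 0.5)
  sp <- reference_spec("linear")
  xr <- integrate_reference(sp, u, 1e-3)
  a <- run_phase(net, u, xr, eta = 2e-4, update_every = 1L)
  b <- run_phase(net, u, xr, eta = 2e-4, update_every = 10L)
  relw <- sqrt(sum((a$net$w_rec - b$net$w_rec)^2)) /
    sqrt(sum(a$net$w_rec^2))
  expect_lt(relw, 0.1)
  expect_equal(mean(a$eps^2), mean(b$eps^2), tolerance = 0.2)
})

test_that("sparsity masks are conserved through learning", {
  set.seed(54)
  net <- follow_network(40, 40, 2, 2, 0.2, 1, connectivity = 0.4)
  set.seed(55)
  u <- babbling_input(2, 1e-3, 2, 0.05, 0.1, pedestal_period = 0.5)
  sp <- reference_spec("linear")
  xr <- integrate_reference(sp, u, 1e-3)
  ph <- run_phase(net, u, xr, eta = 0.1, update_every = 7L)
  expect_true(all(ph$net$w_ff[net$mask_ff == 0] == 0))
  expect_true(all(ph$net$w_rec[net$mask_rec == 0] == 0))
  expect_gt(sum(ph$net$w_rec != 0), 0)
})

test_that("runs are reproducible bit for bit under fixed seeds", {
  run <- function() {
    net <- tiny_network(seed = 60)
    set.seed(61)
    u <- babbling_input(0.5, 1e-3, 2, 0.05, 0.1, pedestal_period = 0.5)
    xr <- matrix(0.1, nrow(u), 2)
    set.seed(62)
    run_phase(net, u, xr, eta = 2e-4, noise_sd = 0.01)
  }
  a <- run(); b <- run()
  expect_identical(a$eps, b$eps)
  expect_identical(a$net$w_rec, b$net$w_rec)
})

test_that("no neuron exceeds the refractory rate bound in any window", {
  net <- tiny_network(n_cmd = 60, n_rec = 60)
  set.seed(56)
  u <- babbling_input(3, 1e-3, 2, 0.1, 0.1, pedestal_period = 1)
  xr <- matrix(0.5, nrow(u), 2)
  ph <- run_phase(net, u, xr, feedback_on = TRUE, plasticity_on = FALSE,
                  rate_bin = 1)
  expect_true(all(ph$rate_bins <= 500))
})

test_that("non-finite commands abort with a diagnostic", {
  net <- tiny_network()
  u <- matrix(Inf, 10, 2)
  xr <- matrix(0, 10, 2)
  expect_error(run_phase(net, u, xr), "non-finite")
})
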