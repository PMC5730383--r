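test_that("weight R2 against the identity line behaves as defined", {
  set.seed(70)
  w <- matrix(rnorm(100), 10, 10)
  expect_equal(weight_r2(w, w), 1)
  # all-zero estimate: R2 = -sum(w^2) / sum((w - mean)^2) <= 0
  expect_equal(weight_r2(matrix(0, 10, 10), w),
               1 - sum(w^2) / sum((w - mean(w))^2))
  expect_lte(weight_r2(matrix(0, 10, 10), w), 0)
  # independent random matrices score near or below zero
  r2s <- replicate(20, weight_r2(matrix(rnorm(100), 10), matrix(rnorm(100), 10)))
  expect_lt(mean(r2s), 0.2)
  expect_error(weight_r2(w, matrix(1, 10, 10)), "zero-variance")
})

test_that("tent map extracts consecutive strict local maxima", {
  t <- seq(0, 20, by = 0.01)
  pairs <- tent_map(sin(2 * pi * t))
  expect_gt(nrow(pairs), 5)
  expect_equal(max(abs(pairs - 1)), 0, tolerance = 1e-4)
  expect_equal(nrow(tent_map(seq_len(100))), 0)
  expect_equal(nrow(tent_map(c(1, 2))), 0)
})

test_that("the Lorenz reference traces a single-humped successive-maxima map", {
  set.seed(71)
  sp <- reference_spec("lorenz", filter_reference = FALSE)
  u <- lorenz_kick(3, 60, 1e-3, 3)
  x <- integrate_reference(sp, u, 1e-3)
  # bounded, and the third coordinate stays above the shifted floor
  expect_true(all(abs(x) < 100))
  expect_true(all(x[5000:nrow(x), 3] + 28 > 0))
  pairs <- tent_map(x[, 3])
  expect_gt(nrow(pairs), 20)
  # unimodal: the map rises on the left branch and falls on the right
  split_pt <- pairs[which.max(pairs[, 2]), 1]
  left <- pairs[pairs[, 1] <= split_pt, , drop = FALSE]
  right <- pairs[pairs[, 1] > split_pt, , drop = FALSE]
  expect_gt(stats::cor(left[, 1], left[, 2]), 0.8)
  expect_lt(stats::cor(right[, 1], right[, 2]), -0.8)
})

test_that("spike alignment scores identical and disjoint rasters correctly", {
  r <- data.frame(neuron = c(1, 1, 2), time = c(0.01, 0.05, 0.02))
  expect_equal(spike_alignment(r, r), 1)
  far <- data.frame(neuron = c(1, 1, 2), time = c(0.5, 0.6, 0.7))
  expect_equal(spike_alignment(r, far), 0)
  expect_true(is.na(spike_alignment(r[0, ], r)))
})

test_that("readout relearning fits the learned network but not shuffled weights", {
  fit <- small_linear_fit()
  rl <- readout_relearn(fit, shuffle = FALSE, duration = 30, seed = 12)
  rs <- readout_relearn(fit, shuffle = TRUE, duration = 30, seed = 12)
  # with eta_r = 0 the readout stays zero
  r0 <- readout_relearn(fit, duration = 2, eta_r = 0, seed = 12)
  expect_true(all(r0$d_learn == 0))
  # perceptron learning reduces the mismatch on the realizable target
  expect_lt(rl$final_mean_abs_error, 0.5 * rl$target_abs)
  # the shuffled network supports the readout strictly worse
  expect_lt(rl$final_mean_abs_error, rs$final_mean_abs_error)
})

test_that("a learner starting at the reference weights sits at the feedback floor", {
  fit <- small_linear_fit()
  cfg <- fit$config
  sp <- fit$spec
  set.seed(13)
  u <- protocol_input(sp, cfg, 12, fit$dt)
  dummy <- matrix(0, nrow(u), 2)
  xref <- run_phase(fit$net, u, dummy, feedback_on = FALSE,
                    plasticity_on = FALSE, record_every = 1L)$xhat
  ph <- run_phase(fit$net, u, xref, feedback_on = TRUE,
                  plasticity_on = FALSE)
  b <- mse_blocks(ph$eps, block = 4)
  # already clamped from the first block: no order-of-magnitude decay left
  expect_lt(b[1], 10 * b[length(b)] + 1e-12)
  expect_lt(mean(abs(ph$eps)), 0.2 * mean(abs(xref)) + 1e-12)
})

test_that("robustness sweep reproduces the unperturbed run at neutral values", {
  base <- list(system = "linear", n_neurons = 60, t_pre = 0.5, t_learn = 8,
               seed = 14)
  sw <- do.call(robustness_sweep,
                c(list(axis = "connectivity", values = 1, seeds = 14), base[-5]))
  plain <- do.call(follow, c(base, list(t_test = 0)))
  nb <- length(plain$block_mse)
  expect_equal(sw$final_mse,
               mean(plain$block_mse[max(1, ceiling(0.8 * nb)):nb]))
  sw2 <- do.call(robustness_sweep,
                 c(list(axis = "decoder_chi", values = 0, seeds = 14), base[-5]))
  expect_equal(sw2$final_mse, sw$final_mse)
  expect_named(sw, c("axis", "value", "seed", "final_mse", "first_mse"))
})
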