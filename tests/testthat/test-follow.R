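test_that("the fitting surface returns a complete, reproducible object", {
  fit <- small_linear_fit()
  expect_s3_class(fit, "follow")
  expect_length(fit$block_mse, 6)
  expect_true(all(fit$block_mse >= 0))
  # methods
  expect_output(print(fit), "FOLLOW forward model")
  s <- summary(fit)
  expect_output(print(s), "clamp")
  co <- coef(fit)
  expect_equal(dim(co$w_rec), c(300, 300))
  expect_equal(dim(co$w_ff), c(300, 300))
  expect_equal(dim(co$decoders), c(2, 300))
  r <- residuals(fit)
  expect_equal(ncol(r), 2)
  expect_equal(nrow(fitted(fit)), length(fit$learn$time))
  grDevices::pdf(NULL)
  plot(fit)
  grDevices::dev.off()
  # learning reduced the open-loop error below the reference scale
  expect_lt(s$test_mean_abs_error, s$test_ref_abs)
})

test_that("identical seeds reproduce identical fits", {
  f1 <- follow("linear", n_neurons = 60, t_pre = 1, t_learn = 5, t_test = 1,
               seed = 9)
  f2 <- follow("linear", n_neurons = 60, t_pre = 1, t_learn = 5, t_test = 1,
               seed = 9)
  expect_identical(f1$block_mse, f2$block_mse)
  expect_identical(f1$net$w_rec, f2$net$w_rec)
  expect_identical(f1$test$eps, f2$test$eps)
})

test_that("without learning the open-loop output stays near zero", {
  fit <- follow("linear", n_neurons = 200, t_pre = 1, t_learn = 4, t_test = 2,
                eta = 0, seed = 10)
  expect_true(all(fit$net$w_rec == 0))
  # only origin-reconstruction noise remains in the decoded output
  expect_lt(mean(abs(fit$test$xhat)), 0.5 * mean(abs(fit$test$x_ref)))
})

test_that("predictions run on matrix, ramp and pulse inputs", {
  fit <- small_linear_fit()
  p1 <- predict(fit, input = "ramp_step", duration = 3, seed = 1)
  expect_s3_class(p1, "follow_prediction")
  expect_equal(nrow(p1$xhat), 3000)
  u <- matrix(0.02, 500, 2)
  p2 <- predict(fit, input = u)
  expect_equal(nrow(p2$xhat), 500)
  p3 <- predict(fit, input = "pulse_pedestal", duration = 2, seed = 2)
  expect_equal(dim(p3$eps), c(2000, 2))
  sims <- simulate(fit, nsim = 2, seed = 3, duration = 1)
  expect_length(sims, 2)
  expect_output(print(p1), "open-loop")
  grDevices::pdf(NULL)
  plot(p1, dim = 2)
  grDevices::dev.off()
})

test_that("block MSE computation matches hand-computed values", {
  eps <- matrix(0, 8000, 2)
  expect_equal(mse_blocks(eps), c(0, 0))
  eps <- cbind(rep(0.1, 8000), rep(0, 8000))
  expect_equal(mse_blocks(eps), c(0.005, 0.005))
  expect_equal(mse_blocks(eps[, 2:1]), mse_blocks(eps))
  expect_error(mse_blocks(eps[1:100, , drop = FALSE]), "shorter")
  # trailing partial blocks are dropped
  expect_length(mse_blocks(matrix(1, 9000, 1)), 2)
})

test_that("rate histograms count spikes over the requested window", {
  empty <- data.frame(neuron = integer(0), time = numeric(0))
  rh <- rate_histogram(empty, n_neurons = 5, window = 0.25)
  expect_equal(rh$rates, rep(0, 5))
  raster <- data.frame(neuron = c(1, 1, 2, 3, 1), time = c(0.1, 0.2, 0.15, 0.4, 0.9))
  rh <- rate_histogram(raster, n_neurons = 3, window = 0.25, t0 = 0.1)
  expect_equal(rh$rates, c(2, 1, 0) / 0.25)
  expect_equal(rh$mean_rate, mean(c(8, 4, 0)))
})

test_that("configurations carry the shipped per-system defaults", {
  cfg <- follow_config("vanderpol")
  expect_equal(cfg$n_neurons, 3000)
  expect_equal(cfg$r1, 0.2)
  expect_equal(cfg$r2, 5)
  expect_equal(cfg$eta, 2e-4)
  cfg2 <- follow_config("lorenz")
  expect_equal(cfg2$n_neurons, 5000)
  expect_equal(cfg2$t_period, 20)
  expect_equal(cfg2$r2, 30)
  expect_error(follow_config("linear", nonsense = 1), "unknown configuration")
})

test_that("YAML configs load with validation and exhaustive errors", {
  shipped <- system.file("extdata", "vanderpol_desk.yaml",
                         package = "follownet")
  cfg0 <- load_config(shipped)
  expect_equal(cfg0$n_neurons, 1000)
  expect_equal(cfg0$r2, 5)
  path <- tempfile(fileext = ".yaml")
  writeLines(c("system: linear", "n_neurons: 500", "eta: 1.0e-4"), path)
  cfg <- load_config(path)
  expect_equal(cfg$n_neurons, 500)
  expect_equal(cfg$eta, 1e-4)
  expect_equal(cfg$r2, 1)          # default filled
  writeLines(c("system: linear", "frobnicate: 1"), path)
  expect_error(load_config(path), "frobnicate")
  writeLines("n_neurons: 500", path)
  expect_error(load_config(path), "system")
  expect_error(load_config(tempfile()), "not found")
})

test_that("runs round-trip through save and load bit for bit", {
  fit <- follow("linear", n_neurons = 40, t_pre = 0.5, t_learn = 4,
                t_test = 0, seed = 11)
  dir <- tempfile()
  save_run(fit, dir)
  back <- load_run(dir)
  expect_identical(back$arrays$w_rec, fit$net$w_rec)
  expect_identical(back$arrays$decoders, fit$net$decoders)
  expect_equal(back$config$n_neurons, 40)
  expect_equal(back$metrics$block_mse, fit$block_mse)
  # tampering is detected
  con <- file(file.path(dir, "metrics.tsv"), "a")
  writeLines("1\t1", con)
  close(con)
  expect_error(load_run(dir), "checksum")
})
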