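#' Fit a spiking forward model with FOLLOW learning
#'
#' Runs the full learning protocol of the FOLLOW scheme against one of
#' the shipped reference dynamical systems and returns a fitted-model
#' object. The protocol has three phases sharing one continuous stream of
#' motor-babbling command input:
#'
#' 1. *Pre-learning* (`t_pre`): error feedback and plasticity off; with
#'    zero initial plastic weights the decoded output stays at zero.
#' 2. *Learning* (`t_learn`): the output error is fed back with gain `k`
#'    (clamping the output to roughly `k/(k+1)` of the reference) and the
#'    feedforward and recurrent weights evolve under the FOLLOW rule.
#' 3. *Testing* (`t_test`): feedback and plasticity off; the network runs
#'    open loop on fresh input with the same statistics.
#'
#' @param system Reference system, see [reference_spec()].
#' @param n_neurons Neurons per layer (default: the shipped full-scale
#'   value from [follow_config()]; scale down for desk runs).
#' @param t_pre,t_learn,t_test Phase durations in seconds.
#' @param eta Learning rate (default from the configuration, 2e-4).
#' @param eta_schedule Optional `list(time =, factor =)`: multiply the
#'   learning rate by `factor` from `time` seconds into the learning
#'   phase onwards.
#' @param scheme Tuning scheme, see [sample_tuning()].
#' @param k Error-feedback gain.
#' @param connectivity Fraction of existing plastic connections.
#' @param decoder_chi,decoder_xi Multiplicative decoder perturbation.
#' @param error_noise_sd Gaussian noise s.d. added to each error component
#'   per step.
#' @param reference_delay Sensory delay of the reference signal (s).
#' @param compensate_delay Also delay the command input to the network by
#'   the same amount (time-translating the protocol).
#' @param filter_reference Low-pass the reference before the error node
#'   (default per system).
#' @param dt Simulation time step (s).
#' @param record_every Trace decimation factor for stored series.
#' @param update_every Steps per blocked weight update (see
#'   [run_phase()]).
#' @param seed Single seed; expanded internally into tuning, input, noise
#'   and test-input streams.
#' @param verbose Print phase progress.
#' @param ... Further overrides passed to [follow_config()] (e.g. `r2`,
#'   `zeta1`, `t_period`).
#' @return An object of class `follow` with, among others, the trained
#'   network (`$net`), the learning curve in 4-s blocks (`$block_mse`),
#'   decimated traces per phase, and the open-loop test run. Use
#'   [summary.follow()], [plot.follow()], [coef.follow()],
#'   [predict.follow()], [residuals.follow()].
#' @export
follow <- function(system = c("vanderpol", "linear", "lorenz",
                              "ff_nonlinear", "arm"),
                   n_neurons = NULL, t_pre = 4, t_learn = 500, t_test = 8,
                   eta = NULL, eta_schedule = NULL,
                   scheme = NULL, k = NULL,
                   connectivity = 1, decoder_chi = 0, decoder_xi = 0,
                   error_noise_sd = 0,
                   reference_delay = 0, compensate_delay = FALSE,
                   filter_reference = NULL, dt = 1e-3,
                   record_every = 10L, update_every = 50L,
                   seed = 1L, verbose = FALSE, ...) {
  system <- match.arg(system)
  t_start <- proc.time()[["elapsed"]]
  cfg <- follow_config(system, ...)
  if (!is.null(n_neurons)) cfg$n_neurons <- n_neurons
  if (!is.null(eta)) cfg$eta <- eta
  if (!is.null(scheme)) cfg$scheme <- scheme
  if (!is.null(k)) cfg$k <- k
  if (!is.null(filter_reference)) cfg$filter_reference <- filter_reference
  spec <- reference_spec(system, filter_reference = cfg$filter_reference)
  seeds <- expand_seeds(seed)

  set.seed(seeds[["tuning"]])
  net <- follow_network(cfg$n_neurons, cfg$n_neurons, spec$nc, spec$nd,
                        cfg$r1, cfg$r2, k = cfg$k, scheme = cfg$scheme,
                        tau_s = cfg$tau_s, tau_eps = cfg$tau_eps,
                        connectivity = connectivity,
                        decoder_chi = decoder_chi, decoder_xi = decoder_xi)

  set.seed(seeds[["input"]])
  u_raw <- protocol_input(spec, cfg, t_pre + t_learn, dt)
  x_net <- integrate_reference(spec, u_raw, dt)
  u_net <- u_raw * spec$input_scale
  prep <- prepare_error_reference(x_net, u_net, spec, cfg, dt,
                                  reference_delay, compensate_delay)

  n_pre <- round(t_pre / dt)
  n_learn <- round(t_learn / dt)
  pre_idx <- seq_len(n_pre)
  learn_idx <- n_pre + seq_len(n_learn)

  set.seed(seeds[["noise"]])
  state <- NULL
  pre <- NULL
  if (n_pre > 0) {
    if (verbose) message("pre-learning phase (", t_pre, " s)")
    pre <- run_phase(net, prep$u[pre_idx, , drop = FALSE],
                     prep$x_err[pre_idx, , drop = FALSE], dt,
                     feedback_on = FALSE, plasticity_on = FALSE,
                     record_every = record_every)
    state <- pre$state
  }
  if (verbose) message("learning phase (", t_learn, " s)")
  eta_steps <- rep(cfg$eta, n_learn)
  if (!is.null(eta_schedule)) {
    from <- round(eta_schedule$time / dt) + 1
    if (from <= n_learn)
      eta_steps[from:n_learn] <- cfg$eta * eta_schedule$factor
  }
  learn <- run_phase(net, prep$u[learn_idx, , drop = FALSE],
                     prep$x_err[learn_idx, , drop = FALSE], dt,
                     feedback_on = TRUE, plasticity_on = TRUE,
                     eta = eta_steps, noise_sd = error_noise_sd,
                     state = state, record_every = record_every,
                     update_every = update_every)
  net <- learn$net

  block_mse <- mse_blocks(learn$eps, dt = dt)
  # clamped closed-loop error level at the start of learning
  nb1 <- min(round(4 / dt), n_learn)
  clamp_abs <- mean(abs(learn$eps[seq_len(nb1), ]))
  ref_abs <- mean(abs(prep$x_err[learn_idx[seq_len(nb1)], ]))

  test <- NULL
  if (t_test > 0) {
    if (verbose) message("test phase (", t_test, " s, open loop)")
    set.seed(seeds[["test"]])
    u_test_raw <- protocol_input(spec, cfg, t_test, dt)
    x0_raw <- x_net[nrow(x_net), ] / spec$state_scale
    x_test <- integrate_reference(spec, u_test_raw, dt, x0 = x0_raw)
    # continue the reference filter from its state at the end of learning
    x_test_err <- if (spec$filter_reference)
      filter_series(x_test, cfg$tau_s, dt,
                    init = prep$x_err[nrow(prep$x_err), ]) else x_test
    test <- run_phase(net, u_test_raw * spec$input_scale, x_test_err, dt,
                      feedback_on = FALSE, plasticity_on = FALSE,
                      state = learn$state, record_every = 1L,
                      spike_windows = matrix(c(0, t_test), 1))
    test$u <- u_test_raw * spec$input_scale
    test$x_ref <- x_test_err
  }

  keep <- function(phase, idx) {
    if (is.null(phase)) return(NULL)
    sel <- seq(1, length(idx), by = record_every)
    list(time = (idx[sel] - 1) * dt,
         u = prep$u[idx[sel], , drop = FALSE],
         x_ref = prep$x_err[idx[sel], , drop = FALSE],
         xhat = phase$xhat,
         eps = phase$eps[sel, , drop = FALSE],
         count_rec = phase$count_rec,
         duration = phase$duration)
  }

  structure(list(
    system = system, config = cfg, spec = spec, seed = seed, seeds = seeds,
    durations = c(pre = t_pre, learn = t_learn, test = t_test), dt = dt,
    net = net,
    block_mse = block_mse,
    block_times = (seq_along(block_mse) - 1) * 4,
    clamp_abs_error = clamp_abs, clamp_ref_abs = ref_abs,
    pre = keep(pre, pre_idx), learn = keep(learn, learn_idx),
    test = test,
    settings = list(connectivity = connectivity, decoder_chi = decoder_chi,
                    decoder_xi = decoder_xi, error_noise_sd = error_noise_sd,
                    reference_delay = reference_delay,
                    compensate_delay = compensate_delay,
                    update_every = update_every,
                    eta_schedule = eta_schedule),
    runtime_s = proc.time()[["elapsed"]] - t_start,
    call = match.call()),
    class = "follow")
}

# Command input stream with the per-system statistics (raw units).
protocol_input <- function(spec, cfg, duration, dt) {
  if (spec$system == "lorenz")
    lorenz_kick(cfg$zeta1, duration, dt, spec$nc)
  else
    babbling_input(duration, dt, spec$nc, cfg$zeta1, cfg$zeta2,
                   pulse_interval = cfg$pulse_interval,
                   pedestal_period = cfg$t_period,
                   interpolate = cfg$interpolate)
}

# Apply sensory delay / compensatory command delay / reference filtering.
prepare_error_reference <- function(x_net, u_net, spec, cfg, dt,
                                    reference_delay, compensate_delay) {
  x_err <- delay_series(x_net, reference_delay, dt)
  u <- if (compensate_delay) delay_series(u_net, reference_delay, dt) else u_net
  if (spec$filter_reference) x_err <- filter_series(x_err, cfg$tau_s, dt)
  list(u = u, x_err = x_err)
}

#' @export
print.follow <- function(x, ...) {
  cat(sprintf("FOLLOW forward model: %s system, %d + %d neurons\n",
              x$system, x$net$cmd$n_neurons, x$net$rec$n_neurons))
  cat(sprintf("  phases: pre %g s | learn %g s | test %g s (dt = %g s)\n",
              x$durations[1], x$durations[2], x$durations[3], x$dt))
  if (length(x$block_mse) >= 2)
    cat(sprintf("  block MSE (4 s): first %.3g, last %.3g (factor %.1f)\n",
                x$block_mse[1], tail(x$block_mse, 1),
                x$block_mse[1] / tail(x$block_mse, 1)))
  invisible(x)
}

#' Summarise a FOLLOW fit
#'
#' Reports the learning curve end points, the closed-loop clamping ratio
#' at the start of learning, mean firing rates, and the open-loop test
#' error.
#' @param object A [follow()] fit.
#' @param ... Unused.
#' @return A `summary.follow` list, printed with its own method.
#' @export
summary.follow <- function(object, ...) {
  s <- list(system = object$system,
            n_neurons = object$net$rec$n_neurons,
            durations = object$durations,
            first_block_mse = object$block_mse[1],
            last_block_mse = tail(object$block_mse, 1),
            mse_drop_factor = object$block_mse[1] / tail(object$block_mse, 1),
            clamp_ratio = object$clamp_abs_error / object$clamp_ref_abs,
            k = object$net$k,
            mean_rate_learn = sum(object$learn$count_rec) /
              object$net$rec$n_neurons / object$learn$duration,
            test_mean_abs_error = if (!is.null(object$test))
              mean(abs(object$test$eps)) else NA_real_,
            test_ref_abs = if (!is.null(object$test))
              mean(abs(object$test$x_ref)) else NA_real_)
  class(s) <- "summary.follow"
  s
}

#' @export
print.summary.follow <- function(x, ...) {
  cat(sprintf("FOLLOW fit, %s system (%d neurons/layer)\n", x$system,
              x$n_neurons))
  cat(sprintf("  learning %g s: block MSE %.3g -> %.3g (drop factor %.1f)\n",
              x$durations[2], x$first_block_mse, x$last_block_mse,
              x$mse_drop_factor))
  cat(sprintf("  closed-loop clamp at learning start: |err|/|ref| = %.3f (1/(k+1) = %.3f)\n",
              x$clamp_ratio, 1 / (x$k + 1)))
  cat(sprintf("  mean firing rate during learning: %.1f Hz\n",
              x$mean_rate_learn))
  if (!is.na(x$test_mean_abs_error))
    cat(sprintf("  open-loop test: mean |err| = %.3g (reference |x| = %.3g)\n",
                x$test_mean_abs_error, x$test_ref_abs))
  invisible(x)
}

#' Extract the learned weights
#'
#' @param object A [follow()] fit.
#' @param ... Unused.
#' @return A list with `w_ff`, `w_rec` and the fixed `decoders`.
#' @export
coef.follow <- function(object, ...) {
  list(w_ff = object$net$w_ff, w_rec = object$net$w_rec,
       decoders = object$net$decoders)
}

#' Open-loop test errors of a FOLLOW fit
#'
#' @param object A [follow()] fit.
#' @param phase `"test"` (full rate) or `"learn"` (decimated).
#' @param ... Unused.
#' @return A matrix of error components over time.
#' @export
residuals.follow <- function(object, phase = c("test", "learn"), ...) {
  phase <- match.arg(phase)
  if (phase == "test") object$test$eps else object$learn$eps
}

#' Fitted (decoded) output during learning
#' @param object A [follow()] fit.
#' @param ... Unused.
#' @return Decimated decoded-output matrix.
#' @export
fitted.follow <- function(object, ...) object$learn$xhat

#' Plot the learning curve of a FOLLOW fit
#'
#' Mean squared error per dimension, averaged over 4-s blocks, on a log
#' scale against learning time.
#' @param x A [follow()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.follow <- function(x, ...) {
  graphics::plot(x$block_times, x$block_mse, log = "y", type = "l",
                 xlab = "learning time (s)",
                 ylab = "block MSE per dimension",
                 main = sprintf("FOLLOW learning curve (%s)", x$system), ...)
  invisible(x)
}

#' Predict the reference dynamics with a trained network
#'
#' Runs the trained network, by default open loop (no error feedback, no
#' plasticity), on a new command input, integrates the reference system
#' under the same input, and returns both trajectories with the
#' prediction error.
#'
#' @param object A [follow()] fit.
#' @param input `"babbling"` (same statistics as training),
#'   `"pulse_pedestal"` (a sharp square pulse at the start of each 4-s
#'   pedestal level), `"ramp_step"` (a 2-s ramp followed by a constant
#'   step), or a `steps x nc` matrix in raw input units.
#' @param duration Duration in seconds (ignored for matrix input).
#' @param feedback Keep the error feedback on (closed loop).
#' @param seed Seed for the input draw.
#' @param from_rest Start network and reference from rest (otherwise the
#'   state at the end of learning is used).
#' @param ... Unused.
#' @return A `follow_prediction`: list with `time`, `u`, `x_ref`
#'   (filtered as during training), `xhat`, `eps`, and the raster of
#'   recurrent-layer spikes.
#' @export
predict.follow <- function(object, input = "babbling", duration = 8,
                           feedback = FALSE, seed = NULL,
                           from_rest = TRUE, ...) {
  spec <- object$spec
  cfg <- object$config
  dt <- object$dt
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(input)) {
    u_raw <- input
    duration <- nrow(u_raw) * dt
  } else {
    u_raw <- switch(match.arg(input, c("babbling", "pulse_pedestal",
                                       "ramp_step")),
      babbling = protocol_input(spec, cfg, duration, dt),
      pulse_pedestal = pulse_pedestal_input(duration, dt, spec$nc,
                                            max(cfg$zeta1), max(cfg$zeta2)),
      ramp_step = ramp_step_input(duration, dt, spec$nc, max(cfg$zeta2)))
  }
  x_ref <- integrate_reference(spec, u_raw, dt)
  x_err <- if (spec$filter_reference) filter_series(x_ref, cfg$tau_s, dt)
           else x_ref
  res <- run_phase(object$net, u_raw * spec$input_scale, x_err, dt,
                   feedback_on = feedback, plasticity_on = FALSE,
                   state = NULL, record_every = 1L,
                   spike_windows = matrix(c(0, duration), 1))
  structure(list(time = res$time, u = u_raw * spec$input_scale,
                 x_ref = x_err, xhat = res$xhat, eps = res$eps,
                 spikes = res$spikes, dt = dt, system = object$system,
                 feedback = feedback),
            class = "follow_prediction")
}

pulse_pedestal_input <- function(duration, dt, nc, zeta1, zeta2,
                                 segment = 4, pulse_len = 0.25) {
  nsteps <- round(duration / dt)
  u <- matrix(0, nsteps, nc)
  seg_steps <- round(segment / dt)
  pulse_steps <- round(pulse_len / dt)
  for (s0 in seq(0, nsteps - 1, by = seg_steps)) {
    dir <- rnorm(nc)
    ped <- zeta2 * dir / sqrt(sum(dir^2))
    idx <- (s0 + 1):min(s0 + seg_steps, nsteps)
    u[idx, ] <- rep(ped, each = length(idx))
    pidx <- (s0 + 1):min(s0 + pulse_steps, nsteps)
    u[pidx, ] <- u[pidx, , drop = FALSE] +
      rep(runif(nc, -zeta1, zeta1), each = length(pidx))
  }
  u
}

ramp_step_input <- function(duration, dt, nc, level, ramp = 2) {
  nsteps <- round(duration / dt)
  dir <- rnorm(nc)
  target <- level * dir / sqrt(sum(dir^2))
  ramp_steps <- min(round(ramp / dt), nsteps)
  w <- c(seq(0, 1, length.out = ramp_steps),
         rep(1, nsteps - ramp_steps))
  outer(w, target)
}

#' @export
print.follow_prediction <- function(x, ...) {
  cat(sprintf("FOLLOW %s-loop prediction (%s system, %.3g s)\n",
              if (x$feedback) "closed" else "open", x$system,
              length(x$time) * x$dt))
  cat(sprintf("  mean |error| %.4g, reference mean |x| %.4g\n",
              mean(abs(x$eps)), mean(abs(x$x_ref))))
  invisible(x)
}

#' @export
plot.follow_prediction <- function(x, dim = 1, ...) {
  graphics::plot(x$time, x$x_ref[, dim], type = "l", col = "blue",
                 xlab = "time (s)", ylab = sprintf("x[%d]", dim),
                 main = sprintf("%s: reference (blue) vs prediction (red)",
                                x$system), ...)
  graphics::lines(x$time, x$xhat[, dim], col = "red")
  invisible(x)
}

#' Simulate open-loop predictions on fresh babbling inputs
#'
#' @param object A [follow()] fit.
#' @param nsim Number of independent input draws.
#' @param seed Optional seed.
#' @param duration Duration of each run (s).
#' @param ... Passed to [predict.follow()].
#' @return A list of `follow_prediction` objects.
#' @export
simulate.follow <- function(object, nsim = 1, seed = NULL, duration = 8,
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    predict(object, input = "babbling", duration = duration, ...))
}
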