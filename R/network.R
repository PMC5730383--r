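#' Construct a FOLLOW network
#'
#' Assembles the two-layer spiking network: a command-representation
#' ensemble projecting through plastic feedforward weights into a
#' recurrent ensemble with plastic recurrent weights, fixed readout
#' decoders, and fixed error-feedback encoders of gain `k`. Plastic
#' weights start at zero. Decoders are solved so that the feedback
#' encoders and the readout form an auto-encoder around the recurrent
#' population; optional multiplicative perturbation of the decoders
#' (`1 + U(-chi + xi, chi + xi)` per entry, drawn once) and optional
#' sparse connectivity masks are applied at construction.
#'
#' @param n_cmd,n_rec Neurons in the command and recurrent layers.
#' @param nc,nd Command and state dimensionalities.
#' @param r1,r2 Representation radii of command and state.
#' @param k Error-feedback gain.
#' @param scheme Tuning scheme, see [sample_tuning()].
#' @param tau_s Synaptic filter time constant (s).
#' @param tau_eps Learning-error filter time constant (s).
#' @param connectivity Fraction of feedforward/recurrent connections that
#'   exist (1 = all-to-all); absent connections stay exactly zero.
#' @param decoder_chi,decoder_xi Width and offset of the multiplicative
#'   decoder perturbation.
#' @param n_decoder_samples Regression samples for [solve_decoders()].
#' @param params Neuron parameters, [lif_params()].
#' @param rate_range Maximum-rate range for the `"intercept_maxrate"`
#'   scheme.
#' @return A `follow_network` object.
#' @export
follow_network <- function(n_cmd, n_rec, nc, nd, r1, r2, k = 10,
                           scheme = "intercept_maxrate",
                           tau_s = 0.020, tau_eps = 0.200,
                           connectivity = 1,
                           decoder_chi = 0, decoder_xi = 0,
                           n_decoder_samples = n_rec,
                           params = lif_params(),
                           rate_range = c(200, 400)) {
  stopifnot(connectivity > 0, connectivity <= 1, k >= 0)
  cmd <- sample_tuning(n_cmd, nc, r1, scheme, params, rate_range)
  rec <- sample_tuning(n_rec, nd, r2, scheme, params, rate_range)
  solve <- solve_decoders(rec, n_decoder_samples)
  decoders <- solve$decoders
  if (decoder_chi > 0 || decoder_xi != 0) {
    gamma <- matrix(runif(length(decoders), -decoder_chi + decoder_xi,
                          decoder_chi + decoder_xi),
                    nrow(decoders), ncol(decoders))
    decoders <- decoders * (1 + gamma)
  }
  mask_ff <- mask_rec <- NULL
  if (connectivity < 1) {
    mask_ff <- matrix(as.numeric(runif(n_rec * n_cmd) < connectivity),
                      n_rec, n_cmd)
    mask_rec <- matrix(as.numeric(runif(n_rec * n_rec) < connectivity),
                       n_rec, n_rec)
  }
  structure(list(cmd = cmd, rec = rec,
                 decoders = decoders, decoder_solve = solve,
                 fb_encoders = scaled_encoders(rec),
                 w_ff = matrix(0, n_rec, n_cmd),
                 w_rec = matrix(0, n_rec, n_rec),
                 mask_ff = mask_ff, mask_rec = mask_rec,
                 k = k, tau_s = tau_s, tau_eps = tau_eps,
                 params = params, nc = nc, nd = nd),
            class = "follow_network")
}

#' @export
print.follow_network <- function(x, ...) {
  cat(sprintf(paste0("FOLLOW network: %d command + %d recurrent LIF neurons, ",
                     "%d-d command, %d-d state, k = %g\n"),
              x$cmd$n_neurons, x$rec$n_neurons, x$nc, x$nd, x$k))
  cat(sprintf("  plastic weight norms: |w_ff| = %.4g, |w_rec| = %.4g\n",
              sqrt(sum(x$w_ff^2)), sqrt(sum(x$w_rec^2))))
  invisible(x)
}

#' Command-layer input currents
#'
#' `J_l = sum_a e_la u_a + b_l` with the gain-scaled command encoders.
#' @param net A [follow_network()].
#' @param u Command vector.
#' @return Current vector for the command layer.
#' @export
command_currents <- function(net, u) {
  if (length(u) != net$nc) stop("dimension mismatch")
  if (!all(is.finite(u))) stop("non-finite command")
  drop(scaled_encoders(net$cmd) %*% u) + net$cmd$biases
}

#' Recurrent-layer input currents
#'
#' `J_i = sum_l w_ff[i,l] cmd_traces[l] + sum_j w_rec[i,j] rec_traces[j] +
#' k * sum_a e_ia err_traces[a] + b_i`, the error term using the
#' synaptically filtered error.
#' @param net A [follow_network()].
#' @param cmd_traces,rec_traces Filtered spike traces of the two layers.
#' @param err_traces Filtered error (length `nd`).
#' @param feedback_on If `FALSE` the error term is dropped.
#' @return Current vector for the recurrent layer.
#' @export
recurrent_currents <- function(net, cmd_traces, rec_traces, err_traces,
                               feedback_on = TRUE) {
  J <- drop(net$w_ff %*% cmd_traces) + drop(net$w_rec %*% rec_traces) +
    net$rec$biases
  if (feedback_on) J <- J + net$k * drop(net$fb_encoders %*% err_traces)
  J
}

#' Decode the network output
#'
#' `xhat_a = sum_i d_ai rec_traces_i`.
#' @param net A [follow_network()] (or a `nd x n` decoder matrix).
#' @param rec_traces Filtered recurrent spike traces.
#' @return The decoded state vector.
#' @export
decode_output <- function(net, rec_traces) {
  D <- if (inherits(net, "follow_network")) net$decoders else net
  drop(D %*% rec_traces)
}

#' One FOLLOW weight increment
#'
#' `dW[i,j] = eta * learn_err_traces[i] * pre_traces[j] * dt` for the
#' feedforward (pre = command traces) and recurrent (pre = recurrent
#' traces) matrices; masked entries stay untouched.
#'
#' @param net A [follow_network()].
#' @param learn_err_traces The kappa_eps-filtered projected error current
#'   per recurrent neuron.
#' @param cmd_traces,rec_traces Filtered presynaptic spike traces.
#' @param eta Learning rate.
#' @param dt Time step (s).
#' @return A list with increments `d_ff` and `d_rec`.
#' @export
follow_update <- function(net, learn_err_traces, cmd_traces, rec_traces,
                          eta, dt) {
  d_ff <- (eta * dt) * tcrossprod(learn_err_traces, cmd_traces)
  d_rec <- (eta * dt) * tcrossprod(learn_err_traces, rec_traces)
  if (!is.null(net$mask_ff)) d_ff <- d_ff * net$mask_ff
  if (!is.null(net$mask_rec)) d_rec <- d_rec * net$mask_rec
  list(d_ff = d_ff, d_rec = d_rec)
}

zero_network_state <- function(net) {
  list(v_cmd = numeric(net$cmd$n_neurons),
       refr_cmd = numeric(net$cmd$n_neurons),
       v_rec = numeric(net$rec$n_neurons),
       refr_rec = numeric(net$rec$n_neurons),
       cmd_traces = numeric(net$cmd$n_neurons),
       rec_traces = numeric(net$rec$n_neurons),
       ff_current = numeric(net$rec$n_neurons),
       rec_current = numeric(net$rec$n_neurons),
       err_traces = numeric(net$nd),
       learn_err_traces = numeric(net$rec$n_neurons))
}

#' Run one protocol phase of a FOLLOW network
#'
#' Iterates the closed-loop tick over a prepared command input and
#' reference series (already delayed and/or filtered as the protocol
#' requires): command-layer LIF step, trace updates, recurrent-layer LIF
#' step, linear decoding, error computation against the reference,
#' error-trace updates and, when plasticity is on, the FOLLOW weight
#' update. Deterministic given the R random seed.
#'
#' @param net A [follow_network()]; the returned copy carries the updated
#'   weights.
#' @param u A `steps x nc` command matrix (network units).
#' @param x_ref A `steps x nd` reference matrix (network units).
#' @param dt Time step (s).
#' @param feedback_on,plasticity_on Phase switches.
#' @param eta Learning rate: a scalar or a per-step vector (schedules).
#'   Follows the reference-simulator convention: applied increments are
#'   scaled by one over the presynaptic population size.
#' @param noise_sd Standard deviation of Gaussian noise added to each
#'   error component per step.
#' @param state Network state carried over from a previous phase
#'   (default: rest).
#' @param record_every Decimation of the recorded output trace.
#' @param update_every Weight increments are accumulated over this many
#'   steps and applied as one blocked update; 1 reproduces the strictly
#'   online rule.
#' @param spike_windows Optional `m x 2` matrix of times (s) delimiting
#'   windows in which recurrent-layer spikes are recorded.
#' @param snapshot_times Optional times (s) at which to snapshot the
#'   plastic weights.
#' @param rate_bin Optional bin width (s) for per-neuron spike counts.
#' @param readout_learning If `TRUE`, the plastic weights are frozen and a
#'   fresh readout matrix is trained online with a perceptron rule against
#'   `x_ref` (see [readout_relearn()]).
#' @param readout_eta Learning rate of the readout perceptron rule.
#' @param d_init Initial readout matrix for `readout_learning`.
#' @param engine `"cpp"` (fast path) or `"r"` (plain-R reference
#'   implementation, for small networks).
#' @return A `follow_phase` list: decimated `xhat`, full-rate `eps`,
#'   spike raster, per-neuron counts, snapshots, the updated `net`,
#'   final `state`, and the inputs used.
#' @export
run_phase <- function(net, u, x_ref, dt = 1e-3,
                      feedback_on = TRUE, plasticity_on = TRUE,
                      eta = 2e-4, noise_sd = 0, state = NULL,
                      record_every = 10L, update_every = 1L,
                      spike_windows = NULL, snapshot_times = NULL,
                      rate_bin = NULL,
                      readout_learning = FALSE, readout_eta = 1e-4,
                      d_init = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(u), is.matrix(x_ref), nrow(u) == nrow(x_ref),
            ncol(u) == net$nc, ncol(x_ref) == net$nd)
  nsteps <- nrow(u)
  eta_steps <- if (length(eta) == 1) rep(eta, nsteps) else eta
  stopifnot(length(eta_steps) == nsteps)
  if (is.null(state)) state <- zero_network_state(net)
  sw <- if (is.null(spike_windows)) {
    matrix(0L, 0, 2)
  } else {
    matrix(as.integer(round(spike_windows / dt)), ncol = 2)
  }
  snap <- if (is.null(snapshot_times)) integer(0)
          else as.integer(round(snapshot_times / dt)) - 1L
  rate_bin_steps <- if (is.null(rate_bin)) 0L else as.integer(round(rate_bin / dt))
  if (is.null(d_init)) d_init <- matrix(0, net$nd, net$rec$n_neurons)

  if (engine == "cpp") {
    res <- cpp_run_network(
      scaled_encoders(net$cmd), net$cmd$biases,
      net$fb_encoders, net$rec$biases,
      net$decoders, net$w_ff, net$w_rec,
      t(u), t(x_ref), state,
      dt, net$params$tau_m, net$params$tau_r, net$tau_s, net$tau_eps,
      net$k, feedback_on, plasticity_on && !readout_learning, eta_steps,
      noise_sd,
      if (is.null(net$mask_ff)) matrix(0, 0, 0) else net$mask_ff,
      if (is.null(net$mask_rec)) matrix(0, 0, 0) else net$mask_rec,
      as.integer(update_every), as.integer(record_every),
      readout_learning, readout_eta, d_init,
      sw, snap, rate_bin_steps)
  } else {
    res <- run_network_r(net, u, x_ref, state, dt, feedback_on,
                         plasticity_on && !readout_learning, eta_steps,
                         noise_sd, record_every, sw, snap,
                         readout_learning, readout_eta, d_init)
  }
  net$w_ff <- res$w_ff
  net$w_rec <- res$w_rec
  structure(list(
    xhat = t(res$xhat), eps = t(res$eps),
    time = (seq_len(nsteps) - 1) * dt,
    record_every = record_every, dt = dt,
    spikes = data.frame(neuron = as.integer(res$spike_neuron),
                        time = as.numeric(res$spike_time)),
    count_cmd = as.integer(res$count_cmd),
    count_rec = as.integer(res$count_rec),
    snapshots = res$snapshots,
    rate_bins = res$rate_bins, rate_bin = rate_bin,
    d_learn = res$d_learn,
    net = net, state = res$state,
    duration = nsteps * dt,
    feedback_on = feedback_on, plasticity_on = plasticity_on),
    class = "follow_phase")
}

# Plain-R reference implementation of the closed-loop tick, following the
# trace-based current formulation literally. Used as an oracle on small
# networks; O(N^2) per step.
run_network_r <- function(net, u, x_ref, state, dt, feedback_on,
                          plasticity_on, eta_steps, noise_sd,
                          record_every, spike_windows, snapshot_steps,
                          readout_learning = FALSE, readout_eta = 1e-4,
                          d_init = NULL) {
  nsteps <- nrow(u)
  p <- net$params
  Ecmd <- scaled_encoders(net$cmd)
  decay_s <- exp(-dt / net$tau_s)
  decay_e <- exp(-dt / net$tau_eps)
  st_cmd <- list(v = state$v_cmd, refractory = state$refr_cmd)
  class(st_cmd) <- "lif_state"
  st_rec <- list(v = state$v_rec, refractory = state$refr_rec)
  class(st_rec) <- "lif_state"
  cmd_tr <- state$cmd_traces; rec_tr <- state$rec_traces
  err_tr <- state$err_traces; learn_err <- state$learn_err_traces
  nrec_pts <- ceiling(nsteps / record_every)
  xhat_rec <- matrix(0, net$nd, nrec_pts)
  eps_full <- matrix(0, net$nd, nsteps)
  spike_n <- integer(0); spike_t <- numeric(0)
  count_cmd <- integer(net$cmd$n_neurons)
  count_rec <- integer(net$rec$n_neurons)
  snapshots <- list()
  d_learn <- d_init
  w_ff <- net$w_ff; w_rec <- net$w_rec
  for (t in seq_len(nsteps)) {
    s1 <- lif_step(st_cmd, command_currents(net, u[t, ]), dt, p)
    st_cmd <- s1$state
    cmd_tr <- cmd_tr * decay_s + s1$spiked / net$tau_s
    count_cmd <- count_cmd + s1$spiked
    J <- drop(w_ff %*% cmd_tr) + drop(w_rec %*% rec_tr) + net$rec$biases
    if (feedback_on) J <- J + net$k * drop(net$fb_encoders %*% err_tr)
    s2 <- lif_step(st_rec, J, dt, p)
    st_rec <- s2$state
    rec_tr <- rec_tr * decay_s + s2$spiked / net$tau_s
    count_rec <- count_rec + s2$spiked
    if (nrow(spike_windows) > 0 && any(s2$spiked)) {
      t0 <- t - 1L
      if (any(t0 >= spike_windows[, 1] & t0 < spike_windows[, 2])) {
        idx <- which(s2$spiked)
        spike_n <- c(spike_n, idx)
        spike_t <- c(spike_t, rep(t * dt, length(idx)))
      }
    }
    xhat <- if (readout_learning) drop(d_learn %*% rec_tr)
            else decode_output(net, rec_tr)
    eps <- x_ref[t, ] - xhat
    if (noise_sd > 0) eps <- eps + rnorm(net$nd, 0, noise_sd)
    eps_full[, t] <- eps
    err_tr <- err_tr * decay_s + eps * (1 - decay_s)
    if (plasticity_on) {
      Ieps <- net$k * drop(net$fb_encoders %*% eps)
      learn_err <- learn_err * decay_e + Ieps * (1 - decay_e)
      netw <- net; netw$w_ff <- w_ff; netw$w_rec <- w_rec
      inc <- follow_update(netw, learn_err, cmd_tr, rec_tr, eta_steps[t], dt)
      # reference-simulator convention: increments scaled by 1/n_pre
      w_ff <- w_ff + inc$d_ff / net$cmd$n_neurons
      w_rec <- w_rec + inc$d_rec / net$rec$n_neurons
    }
    if (readout_learning)
      d_learn <- d_learn - (readout_eta * dt) *
        tcrossprod(drop(d_learn %*% rec_tr) - x_ref[t, ], rec_tr)
    if ((t - 1L) %% record_every == 0L)
      xhat_rec[, (t - 1L) %/% record_every + 1L] <- xhat
    if ((t - 1L) %in% snapshot_steps)
      snapshots[[length(snapshots) + 1L]] <-
        list(step = t, w_ff = w_ff, w_rec = w_rec)
  }
  list(xhat = xhat_rec, eps = eps_full, w_ff = w_ff, w_rec = w_rec,
       state = list(v_cmd = st_cmd$v, refr_cmd = st_cmd$refractory,
                    v_rec = st_rec$v, refr_rec = st_rec$refractory,
                    cmd_traces = cmd_tr, rec_traces = rec_tr,
                    ff_current = drop(w_ff %*% cmd_tr),
                    rec_current = drop(w_rec %*% rec_tr),
                    err_traces = err_tr, learn_err_traces = learn_err),
       spike_neuron = spike_n, spike_time = spike_t,
       count_cmd = count_cmd, count_rec = count_rec,
       snapshots = snapshots, rate_bins = NULL, d_learn = d_learn)
}
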