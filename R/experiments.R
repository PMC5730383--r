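#' Block-averaged mean squared error
#'
#' Mean over time and over output dimensions of the squared error, per
#' consecutive block (4 s by default, the resolution used for learning
#' curves). A trailing incomplete block is dropped.
#'
#' @param eps A `steps x nd` error matrix.
#' @param dt Time step (s).
#' @param block Block length (s).
#' @return A vector of per-block MSE values.
#' @export
mse_blocks <- function(eps, dt = 1e-3, block = 4) {
  bs <- round(block / dt)
  if (nrow(eps) < bs) stop("series shorter than one block")
  nb <- nrow(eps) %/% bs
  sq <- rowMeans(eps^2)
  vapply(seq_len(nb), function(b) mean(sq[((b - 1) * bs + 1):(b * bs)]),
         numeric(1))
}

#' Per-neuron firing rates over a window
#'
#' Spike counts in `[t0, t0 + window)` divided by the window length, for
#' every neuron of the population.
#'
#' @param spikes A raster data frame with columns `neuron` and `time`
#'   (s), as returned in `$spikes` of [run_phase()] /
#'   [predict.follow()].
#' @param n_neurons Population size.
#' @param window Window length (s).
#' @param t0 Window start (s).
#' @return A list with per-neuron `rates` (Hz) and their `mean_rate`.
#' @export
rate_histogram <- function(spikes, n_neurons, window, t0 = 0) {
  stopifnot(window > 0)
  sel <- spikes$time >= t0 & spikes$time < t0 + window
  counts <- tabulate(spikes$neuron[sel], nbins = n_neurons)
  rates <- counts / window
  list(rates = rates, mean_rate = mean(rates), window = window, t0 = t0)
}

#' Coefficient of determination against the identity line
#'
#' `R^2 = 1 - sum((learned - ref)^2) / sum((ref - mean(ref))^2)`: 1 for
#' identical matrices, near or below 0 for unrelated ones.
#'
#' @param learned,reference Matrices of the same shape.
#' @return The scalar R^2.
#' @export
weight_r2 <- function(learned, reference) {
  stopifnot(all(dim(learned) == dim(reference)))
  ss_ref <- sum((reference - mean(reference))^2)
  if (ss_ref == 0) stop("zero-variance reference weights")
  1 - sum((learned - reference)^2) / ss_ref
}

#' Learn a realizable reference: a frozen FOLLOW-trained network
#'
#' Replaces the differential-equation reference by a spiking network of
#' identical architecture: the frozen, previously trained network is run
#' open loop on the babbling input to produce the reference trajectory,
#' and a learner with the same neurons, encoders and decoders but zero
#' plastic weights is trained against it with FOLLOW. Because exact
#' solution weights exist, the error can approach zero and the learned
#' weights can be compared entry-wise with the reference weights.
#'
#' @param reference A trained [follow()] fit whose network serves as the
#'   frozen realizable reference.
#' @param t_learn Learning duration (s).
#' @param snapshot_times Times (s) at which weight snapshots are taken
#'   for the R^2-versus-time curve.
#' @param seed Seed for the babbling input.
#' @param update_every Blocked-update interval, see [run_phase()].
#' @return A `realizable_result`: learning-curve blocks, `r2_ff` /
#'   `r2_rec` per snapshot, final weights, and a spike-time alignment
#'   summary between matched neurons under identical input with feedback
#'   on (`alignment`, fraction of learner spikes within 2 ms of a
#'   reference spike of the same neuron).
#' @export
realizable_protocol <- function(reference, t_learn = 200,
                                snapshot_times = NULL, seed = 1,
                                update_every = 10L) {
  spec <- reference$spec
  cfg <- reference$config
  dt <- reference$dt
  ref_net <- reference$net
  if (is.null(snapshot_times))
    snapshot_times <- unique(round(seq(t_learn / 5, t_learn, length.out = 5)))
  set.seed(seed)
  u_raw <- protocol_input(spec, cfg, t_learn, dt)
  u_net <- u_raw * spec$input_scale
  dummy <- matrix(0, nrow(u_net), spec$nd)
  ref_run <- run_phase(ref_net, u_net, dummy, dt, feedback_on = FALSE,
                       plasticity_on = FALSE, record_every = 1L)
  # frozen network output; filtered before the error node under the same
  # convention as the differential-equation references
  x_ref <- ref_run$xhat
  if (spec$filter_reference) x_ref <- filter_series(x_ref, cfg$tau_s, dt)

  learner <- ref_net
  learner$w_ff[] <- 0
  learner$w_rec[] <- 0
  learn <- run_phase(learner, u_net, x_ref, dt, feedback_on = TRUE,
                     plasticity_on = TRUE, eta = cfg$eta,
                     record_every = 10L, update_every = update_every,
                     snapshot_times = snapshot_times)
  r2_ff <- vapply(learn$snapshots,
                  function(s) weight_r2(s$w_ff, ref_net$w_ff), numeric(1))
  r2_rec <- vapply(learn$snapshots,
                   function(s) weight_r2(s$w_rec, ref_net$w_rec), numeric(1))

  # spike-time alignment under identical input, feedback on
  t_align <- min(4, t_learn)
  ua <- u_net[seq_len(round(t_align / dt)), , drop = FALSE]
  xa <- x_ref[seq_len(round(t_align / dt)), , drop = FALSE]
  ref_spk <- run_phase(ref_net, ua, xa, dt, feedback_on = FALSE,
                       plasticity_on = FALSE, record_every = 10L,
                       spike_windows = matrix(c(0, t_align), 1))$spikes
  lrn_spk <- run_phase(learn$net, ua, xa, dt, feedback_on = TRUE,
                       plasticity_on = FALSE, record_every = 10L,
                       spike_windows = matrix(c(0, t_align), 1))$spikes
  structure(list(block_mse = mse_blocks(learn$eps, dt = dt),
                 snapshot_times = snapshot_times,
                 r2_ff = r2_ff, r2_rec = r2_rec,
                 net = learn$net, reference_net = ref_net,
                 eps = learn$eps[seq(1, nrow(learn$eps), by = 10), ,
                                 drop = FALSE],
                 alignment = spike_alignment(lrn_spk, ref_spk,
                                             tol = 2e-3)),
            class = "realizable_result")
}

#' Fraction of spikes aligned between two rasters
#'
#' For each spike of `raster` the nearest spike of the same neuron index
#' in `reference` is sought; returns the fraction within `tol` seconds.
#' @param raster,reference Spike data frames (`neuron`, `time`).
#' @param tol Alignment tolerance (s).
#' @return The aligned fraction (NA when `raster` is empty).
#' @export
spike_alignment <- function(raster, reference, tol = 2e-3) {
  if (nrow(raster) == 0) return(NA_real_)
  ref_by <- split(reference$time, reference$neuron)
  hits <- mapply(function(n, t) {
    rt <- ref_by[[as.character(n)]]
    if (is.null(rt)) FALSE else min(abs(rt - t)) <= tol
  }, raster$neuron, raster$time)
  mean(hits)
}

#' Relearn the readout with the plastic weights fixed
#'
#' Tests whether the specific learned weight matrices, and not merely
#' their value distribution, carry the computation: the network is run
#' open loop (no feedback) with its plastic weights either as learned or
#' with their entries randomly permuted, and a fresh readout is trained
#' from zero with a perceptron rule against the learned network's own
#' decoded output. With the learned weights the target is realizable by
#' construction; with shuffled weights the network dynamics no longer
#' supports it.
#'
#' @param fit A trained [follow()] fit.
#' @param shuffle Permute the (nonzero) entries of both plastic matrices.
#' @param duration Training duration (s).
#' @param eta_r Perceptron learning rate for the readout.
#' @param seed Seed for the babbling input and the permutation.
#' @return A list with the readout `d_learn`, the full-rate readout
#'   error, and `final_mean_abs_error` over the last 20 % of the run.
#' @export
readout_relearn <- function(fit, shuffle = FALSE, duration = 50,
                            eta_r = 1e-4, seed = 1) {
  spec <- fit$spec
  cfg <- fit$config
  dt <- fit$dt
  set.seed(seed)
  u_raw <- protocol_input(spec, cfg, duration, dt)
  u_net <- u_raw * spec$input_scale
  dummy <- matrix(0, nrow(u_net), spec$nd)
  target <- run_phase(fit$net, u_net, dummy, dt, feedback_on = FALSE,
                      plasticity_on = FALSE, record_every = 1L)$xhat

  net <- fit$net
  if (shuffle) {
    shuf <- function(w) {
      nz <- w != 0
      w[nz] <- sample(w[nz])
      w
    }
    net$w_ff <- shuf(net$w_ff)
    net$w_rec <- shuf(net$w_rec)
  }
  res <- run_phase(net, u_net, target, dt, feedback_on = FALSE,
                   plasticity_on = FALSE, record_every = 10L,
                   readout_learning = TRUE, readout_eta = eta_r)
  tail_idx <- seq(round(0.8 * nrow(res$eps)) + 1, nrow(res$eps))
  list(d_learn = res$d_learn,
       eps = res$eps,
       target_abs = mean(abs(target)),
       final_mean_abs_error = mean(abs(res$eps[tail_idx, ])),
       shuffled = shuffle)
}

#' Robustness sweep over a perturbation axis
#'
#' Re-runs the learning protocol while varying one robustness parameter
#' (sparse connectivity, error noise, multiplicative decoder
#' perturbation width or offset, sensory delay with or without a
#' compensatory command delay) and records the mean squared error over
#' the final 20 % of learning.
#'
#' @param axis One of `"connectivity"`, `"error_noise"`, `"decoder_chi"`,
#'   `"decoder_xi"`, `"delay"`, `"delay_compensated"`.
#' @param values Parameter values to sweep.
#' @param seeds Seeds; each value is run once per seed.
#' @param ... Base arguments passed to [follow()] (system, sizes,
#'   durations, ...).
#' @return A data frame with `value`, `seed`, `final_mse`, and the
#'   first-block MSE for reference.
#' @export
robustness_sweep <- function(axis = c("connectivity", "error_noise",
                                      "decoder_chi", "decoder_xi",
                                      "delay", "delay_compensated"),
                             values, seeds = 1:3, ...) {
  axis <- match.arg(axis)
  base <- list(...)
  rows <- list()
  for (v in values) for (s in seeds) {
    args <- base
    args$seed <- s
    args$t_test <- 0
    args <- c(args, switch(axis,
      connectivity = list(connectivity = v),
      error_noise = list(error_noise_sd = v),
      decoder_chi = list(decoder_chi = v),
      decoder_xi = list(decoder_chi = 2, decoder_xi = v),
      delay = list(reference_delay = v),
      delay_compensated = list(reference_delay = v,
                               compensate_delay = TRUE)))
    fit <- do.call(follow, args)
    nb <- length(fit$block_mse)
    last <- fit$block_mse[max(1, ceiling(0.8 * nb)):nb]
    rows[[length(rows) + 1]] <-
      data.frame(axis = axis, value = v, seed = s,
                 final_mse = mean(last), first_mse = fit$block_mse[1])
  }
  do.call(rbind, rows)
}

#' Successive-maxima (tent) map of a scalar series
#'
#' Detects strict local maxima and returns consecutive pairs
#' `(max_n, max_{n+1})`. Applied to the third component of the Lorenz
#' system this traces the classic single-humped tent curve. An optional
#' moving-average window smooths spike-level jitter in decoded outputs
#' before detection.
#'
#' @param x Scalar time series.
#' @param smooth Optional moving-average window length (samples).
#' @return A two-column matrix of consecutive maxima pairs (zero rows if
#'   fewer than two maxima exist).
#' @export
tent_map <- function(x, smooth = 0) {
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    x <- stats::filter(x, k, sides = 2)
    x <- x[!is.na(x)]
  }
  n <- length(x)
  if (n < 3) return(matrix(numeric(0), 0, 2,
                           dimnames = list(NULL, c("max_n", "max_n1"))))
  i <- 2:(n - 1)
  peaks <- x[i][x[i] > x[i - 1] & x[i] > x[i + 1]]
  if (length(peaks) < 2)
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("max_n", "max_n1"))))
  cbind(max_n = peaks[-length(peaks)], max_n1 = peaks[-1])
}
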