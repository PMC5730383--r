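#' Leaky integrate-and-fire neuron parameters
#'
#' @param tau_m Membrane time constant in seconds.
#' @param tau_r Absolute refractory period in seconds.
#' @param threshold Firing threshold (dimensionless voltage).
#' @param v_reset Reset voltage after a spike.
#' @param v_floor Lower clip for the voltage.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 0.020, tau_r = 0.002, threshold = 1,
                       v_reset = 0, v_floor = 0) {
  stopifnot(tau_m > 0, tau_r >= 0, threshold > 0,
            v_reset <= v_floor, v_floor <= threshold)
  structure(list(tau_m = tau_m, tau_r = tau_r, threshold = threshold,
                 v_reset = v_reset, v_floor = v_floor),
            class = "lif_params")
}

#' Static LIF gain function
#'
#' Steady-state firing rate of a leaky integrate-and-fire neuron with
#' absolute refractoriness driven by a constant current `J`:
#' zero for `J <= threshold` and
#' `1 / (tau_r + tau_m * log(J / (J - threshold)))` above it.
#'
#' @param J Constant input current (vectorised).
#' @param params A [lif_params()] object.
#' @return Firing rate(s) in Hz.
#' @export
lif_rate <- function(J, params = lif_params()) {
  stopifnot(all(is.finite(J)))
  r <- numeric(length(J))
  sup <- J > params$threshold
  r[sup] <- 1 / (params$tau_r +
                   params$tau_m * log(J[sup] / (J[sup] - params$threshold)))
  r
}

#' Create the state of a LIF population
#'
#' @param n Number of neurons.
#' @param v Optional initial voltages (recycled).
#' @return A `lif_state` with voltages and refractory clocks.
#' @export
lif_state <- function(n, v = 0) {
  structure(list(v = rep_len(v, n), refractory = numeric(n)),
            class = "lif_state")
}

#' Advance a LIF population by one time step
#'
#' Exact exponential integration of `tau_m dV/dt = -V + J` over the
#' non-refractory fraction of the step. When the voltage crosses threshold
#' the crossing time inside the step is recovered by inverting the
#' exponential solution, the voltage is reset and the refractory clock is
#' started from the crossing time, so firing rates are free of step-size
#' quantisation bias. Voltages are clipped at `v_floor`.
#'
#' @param state A [lif_state()].
#' @param J Current vector (one entry per neuron).
#' @param dt Time step in seconds.
#' @param params A [lif_params()].
#' @return A list with the updated `state` and a logical `spiked` vector.
#' @export
lif_step <- function(state, J, dt, params = lif_params()) {
  if (!all(is.finite(J)))
    stop("non-finite input current: numerical blow-up upstream")
  stopifnot(dt > 0, length(J) == length(state$v))
  th <- params$threshold
  refr <- pmax(state$refractory - dt, -dt)
  delta <- pmin(pmax(dt - refr, 0), dt)
  v <- state$v - (J - state$v) * expm1(-delta / params$tau_m)
  spiked <- v > th
  if (any(spiked)) {
    t_spike <- dt + params$tau_m *
      log1p(-(v[spiked] - th) / (J[spiked] - th))
    v[spiked] <- params$v_reset
    refr[spiked] <- params$tau_r + t_spike
  }
  v[v < params$v_floor] <- params$v_floor
  state$v <- v
  state$refractory <- refr
  list(state = state, spiked = spiked)
}

#' Sample a heterogeneous tuning ensemble
#'
#' Draws per-neuron gains, biases and normalised encoding vectors for a
#' population representing a `dim`-dimensional variable whose norm is
#' bounded by `radius`. Encoders are uniform on the hypersphere of radius
#' `1/radius`, so projections of represented points lie in `[-1, 1]`.
#'
#' Two schemes are provided. `"intercept_maxrate"` draws the normalised
#' projection at which firing starts (the intercept) uniformly from
#' `[-1, 1)` and the rate at projection 1 uniformly from `rate_range`
#' (Hz), then solves the gain and bias from the static gain function.
#' `"fixed_gain"` sets every gain to 2 and draws biases uniformly from
#' `[-2, 2)`.
#'
#' @param n Number of neurons.
#' @param dim Represented dimensionality.
#' @param radius Representation radius of the encoded variable.
#' @param scheme Tuning scheme, see Details.
#' @param params A [lif_params()] (threshold enters the inversion).
#' @param rate_range Range of maximum rates for `"intercept_maxrate"`.
#' @return A `tuning_ensemble` with fields `gains`, `biases`, `encoders`
#'   (rows of norm `1/radius`), `radius`, `scheme`.
#' @export
sample_tuning <- function(n, dim, radius,
                          scheme = c("intercept_maxrate", "fixed_gain"),
                          params = lif_params(), rate_range = c(200, 400)) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 1, dim >= 1, radius > 0)
  enc <- matrix(rnorm(n * dim), n, dim)
  enc <- enc / sqrt(rowSums(enc^2)) / radius
  th <- params$threshold
  if (scheme == "fixed_gain") {
    gains <- rep(2, n)
    biases <- runif(n, -2, 2)
  } else {
    intercept <- runif(n, -1, 1)
    max_rate <- runif(n, rate_range[1], rate_range[2])
    # invert g(J) = r: J at which the static rate equals max_rate
    z <- (1 / max_rate - params$tau_r) / params$tau_m
    J_max <- th / (1 - exp(-z))
    gains <- (J_max - th) / (1 - intercept)
    biases <- th - gains * intercept
  }
  structure(list(n_neurons = n, dim = dim, radius = radius, scheme = scheme,
                 gains = gains, biases = biases, encoders = enc,
                 params = params),
            class = "tuning_ensemble")
}

#' @export
print.tuning_ensemble <- function(x, ...) {
  cat(sprintf("Tuning ensemble: %d LIF neurons, %d-d, radius %g, scheme '%s'\n",
              x$n_neurons, x$dim, x$radius, x$scheme))
  invisible(x)
}

#' Scaled encoders of an ensemble
#'
#' Gain-scaled encoding matrix `E = diag(gains) %*% encoders`, mapping a
#' represented point to the per-neuron input currents (before bias).
#' @param ensemble A [sample_tuning()] ensemble.
#' @return An `n_neurons x dim` matrix.
#' @export
scaled_encoders <- function(ensemble) {
  ensemble$encoders * ensemble$gains
}

#' Static firing rates of an ensemble at a represented point
#'
#' Rates from the static gain function at currents
#' `E %*% point + biases`, where `E` are the gain-scaled encoders (or an
#' override matrix).
#'
#' @param ensemble A [sample_tuning()] ensemble.
#' @param point Represented vector, or a matrix with one point per row.
#' @param encoders_override Optional replacement for the scaled encoders.
#' @return A rate vector (or matrix, points in rows) in Hz.
#' @export
static_rates <- function(ensemble, point, encoders_override = NULL) {
  E <- if (is.null(encoders_override)) scaled_encoders(ensemble)
       else encoders_override
  if (is.matrix(point)) {
    if (ncol(point) != ncol(E)) stop("dimension mismatch")
    J <- tcrossprod(point, E) + rep(ensemble$biases, each = nrow(point))
    matrix(lif_rate(J, ensemble$params), nrow(point), ensemble$n_neurons)
  } else {
    if (length(point) != ncol(E)) stop("dimension mismatch")
    lif_rate(drop(E %*% point) + ensemble$biases, ensemble$params)
  }
}
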