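#' Exponential synaptic filter state
#'
#' First-order low-pass with kernel `exp(-t/tau)/tau` (unit area, unit DC
#' gain).
#' @param n Number of parallel traces.
#' @param tau Filter time constant in seconds.
#' @return An `exp_filter` state.
#' @export
exp_filter <- function(n, tau) {
  stopifnot(tau > 0)
  structure(list(tau = tau, trace = numeric(n)), class = "exp_filter")
}

#' Advance an exponential filter by one step
#'
#' Exact update: the trace decays by `exp(-dt/tau)`, spikes of unit area
#' add `impulse_area / tau`, and continuous inputs enter with gain
#' `1 - exp(-dt/tau)` so the DC gain is exactly 1 at any step size.
#'
#' @param state An [exp_filter()] state.
#' @param impulse_area Impulse areas arriving this step (e.g. spike
#'   indicators), recycled.
#' @param continuous_input Continuous input values, recycled.
#' @param dt Time step in seconds.
#' @return The updated state.
#' @export
exp_filter_step <- function(state, impulse_area = 0, continuous_input = 0, dt) {
  stopifnot(dt > 0)
  decay <- exp(-dt / state$tau)
  state$trace <- state$trace * decay + impulse_area / state$tau +
    continuous_input * (1 - decay)
  state
}

#' Motor-babbling command input
#'
#' Random exploratory commands on two time scales: every `pulse_interval`
#' each component is redrawn uniformly from `(-zeta1, zeta1)`, and every
#' `pedestal_period` a slowly varying pedestal is redrawn. With a scalar
#' `zeta2` the pedestal is a vector of norm `zeta2` in a uniformly random
#' direction; with a per-component `zeta2` each component is drawn with
#' its own amplitude and a random sign. The command is the sum of pulse
#' and pedestal, piecewise constant, or linearly interpolated between the
#' `pulse_interval` draws when `interpolate = TRUE`.
#'
#' @param duration Total duration in seconds.
#' @param dt Time step in seconds.
#' @param n_comp Number of command components.
#' @param zeta1 Fast pulse amplitude bound (scalar or per component).
#' @param zeta2 Pedestal amplitude: vector norm if scalar, per-component
#'   amplitudes if a vector of length `n_comp`.
#' @param pulse_interval Redraw interval of the fast pulses (s).
#' @param pedestal_period Redraw period of the pedestal (s).
#' @param interpolate Linearly interpolate between draws (used for the
#'   arm, where sharp switching would excite oscillations).
#' @return A `steps x n_comp` matrix of commands, one row per time step.
#' @export
babbling_input <- function(duration, dt, n_comp, zeta1, zeta2,
                           pulse_interval = 0.050, pedestal_period = 1,
                           interpolate = FALSE) {
  stopifnot(duration > 0, dt > 0, all(zeta1 >= 0), all(zeta2 >= 0),
            pulse_interval > 0, pedestal_period >= pulse_interval)
  nsteps <- round(duration / dt)
  pulse_steps <- round(pulse_interval / dt)
  ped_every <- round(pedestal_period / pulse_interval)
  nknots <- ceiling(nsteps / pulse_steps) + 1L
  zeta1 <- rep_len(zeta1, n_comp)
  per_comp <- length(zeta2) > 1
  zeta2 <- rep_len(zeta2, n_comp)

  knots <- matrix(0, nknots, n_comp)
  ped <- numeric(n_comp)
  for (i in seq_len(nknots)) {
    if ((i - 1L) %% ped_every == 0L) {
      if (per_comp) {
        ped <- zeta2 * sign(runif(n_comp) - 0.5)
      } else if (zeta2[1] > 0) {
        dir <- rnorm(n_comp)
        ped <- zeta2[1] * dir / sqrt(sum(dir^2))
      } else ped <- numeric(n_comp)
    }
    pulse <- runif(n_comp, -zeta1, zeta1)
    knots[i, ] <- ped + pulse
  }
  u <- matrix(0, nsteps, n_comp)
  step_idx <- seq_len(nsteps) - 1L
  ki <- step_idx %/% pulse_steps + 1L
  if (interpolate) {
    frac <- (step_idx %% pulse_steps) / pulse_steps
    for (a in seq_len(n_comp))
      u[, a] <- knots[ki, a] * (1 - frac) + knots[ki + 1L, a] * frac
  } else {
    u[] <- knots[ki, , drop = FALSE]
  }
  u
}

#' Initial kick input for autonomous dynamics
#'
#' A constant vector of norm `zeta1` in a uniformly random direction for
#' the first 0.25 s, zero afterwards; used to set off the Lorenz system,
#' which then runs autonomously.
#'
#' @param zeta1 Kick norm.
#' @param duration Total duration in seconds.
#' @param dt Time step in seconds.
#' @param n_comp Number of components.
#' @param kick_duration Duration of the kick (s).
#' @return A `steps x n_comp` matrix.
#' @export
lorenz_kick <- function(zeta1, duration, dt, n_comp = 3,
                        kick_duration = 0.250) {
  nsteps <- round(duration / dt)
  u <- matrix(0, nsteps, n_comp)
  nk <- min(round(kick_duration / dt), nsteps)
  if (zeta1 > 0 && nk > 0) {
    dir <- rnorm(n_comp)
    u[seq_len(nk), ] <- rep(zeta1 * dir / sqrt(sum(dir^2)), each = nk)
  }
  u
}

#' Pure delay line
#'
#' @param delay Delay in seconds (an integer number of steps).
#' @param dt Time step in seconds.
#' @param n Number of parallel signals.
#' @return A `delay_line` state with a zero-initialised buffer.
#' @export
delay_line <- function(delay, dt, n = 1) {
  stopifnot(delay >= 0)
  steps <- round(delay / dt)
  if (abs(steps * dt - delay) > 1e-9 * max(dt, delay))
    stop("delay must be an integer number of steps")
  structure(list(steps = steps, buffer = matrix(0, max(steps, 1), n),
                 pos = 0L, n = n), class = "delay_line")
}

#' Push a value through a delay line
#'
#' Returns the value from `delay` seconds ago (zero during the initial
#' transient); zero delay is the identity.
#' @param line A [delay_line()].
#' @param value Current input (length `n`).
#' @return A list with the delayed `value` and the updated `line`.
#' @export
delay_step <- function(line, value) {
  if (line$steps == 0L) return(list(value = value, line = line))
  pos <- line$pos %% line$steps + 1L
  out <- line$buffer[pos, ]
  line$buffer[pos, ] <- value
  line$pos <- line$pos + 1L
  list(value = out, line = line)
}

#' Shift a signal matrix by a delay
#'
#' Row `t` of the result is row `t - delay/dt` of `x` (zeros, or
#' `pad` recycled, during the initial transient). Used to apply sensory
#' or compensatory delays to whole recorded series.
#' @param x A `steps x d` matrix.
#' @param delay Delay in seconds.
#' @param dt Time step in seconds.
#' @param pad Value filling the first `delay/dt` rows.
#' @return The shifted matrix.
#' @export
delay_series <- function(x, delay, dt, pad = 0) {
  steps <- round(delay / dt)
  if (steps == 0) return(x)
  out <- matrix(pad, nrow(x), ncol(x))
  if (steps < nrow(x))
    out[(steps + 1):nrow(x), ] <- x[seq_len(nrow(x) - steps), , drop = FALSE]
  out
}
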