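#' Two-link arm parameters
#'
#' Masses, lengths, joint-to-centre-of-mass distances, inertias, joint
#' damping and gravity for a human-scale two-link arm moving in the
#' vertical plane (shoulder joint at the top, elbow in between).
#'
#' @param m1,m2 Link masses (kg).
#' @param l1,l2 Link lengths (m).
#' @param s1,s2 Joint-to-centre-of-mass distances (m).
#' @param I1,I2 Moments of inertia (kg m^2).
#' @param b11,b12,b21,b22 Joint damping coefficients (kg m^2 / s).
#' @param g Gravitational acceleration (m / s^2).
#' @return An `arm_params` object.
#' @export
arm_params <- function(m1 = 1.4, m2 = 1.1, l1 = 0.3, l2 = 0.33,
                       s1 = 0.11, s2 = 0.16, I1 = 0.025, I2 = 0.045,
                       b11 = 0.05, b12 = 0.025, b21 = 0.025, b22 = 0.05,
                       g = 9.81) {
  stopifnot(m1 > 0, m2 > 0, l1 > 0, l2 > 0, s1 > 0, s2 > 0, I1 > 0, I2 > 0)
  structure(list(m1 = m1, m2 = m2, l1 = l1, l2 = l2, s1 = s1, s2 = s2,
                 I1 = I1, I2 = I2, b11 = b11, b12 = b12, b21 = b21,
                 b22 = b22, g = g), class = "arm_params")
}

arm_par_vec <- function(p) {
  c(p$m1, p$m2, p$l1, p$l2, p$s1, p$s2, p$I1, p$I2,
    p$b11, p$b12, p$b21, p$b22, p$g)
}

#' Reference dynamical systems
#'
#' Describes which reference system the network must learn, with its
#' dimensionalities and scalings. Shipped systems: `"linear"` (decaying
#' oscillator), `"vanderpol"`, `"lorenz"` (third coordinate shifted so the
#' observables vary around zero), `"ff_nonlinear"` (the linear system
#' driven through an odd cubic input non-linearity), and `"arm"` (two-link
#' arm under gravity, with torques clipped near the +/-90 degree limits).
#' For the arm, torques, angular velocities and angles are scaled by
#' 0.02, 0.05 and 1/2.5 to dimensionless network units, and the network
#' command is un-scaled to raw torque before integration.
#'
#' @param system System name.
#' @param params For the arm, an [arm_params()] object.
#' @param filter_reference Pass the reference through the synaptic filter
#'   before the error node (default: on, except for the arm).
#' @param x0 Initial state in raw units (defaults to the origin).
#' @return A `reference_spec`.
#' @export
reference_spec <- function(system = c("linear", "vanderpol", "lorenz",
                                      "ff_nonlinear", "arm"),
                           params = NULL, filter_reference = NULL,
                           x0 = NULL) {
  system <- match.arg(system)
  code <- match(system, c("linear", "vanderpol", "lorenz", "ff_nonlinear",
                          "arm"))
  nd <- c(2, 2, 3, 2, 4)[code]
  nc <- c(2, 2, 3, 2, 2)[code]
  if (system == "arm" && is.null(params)) params <- arm_params()
  if (is.null(filter_reference)) filter_reference <- system != "arm"
  if (is.null(x0)) x0 <- numeric(nd)
  # command scaling: network command = input_scale * raw input
  input_scale <- if (system == "arm") 0.02 else 1
  state_scale <- if (system == "arm") c(1 / 2.5, 1 / 2.5, 0.05, 0.05)
                 else rep(1, nd)
  structure(list(system = system, code = code, nd = nd, nc = nc,
                 params = params, filter_reference = filter_reference,
                 input_scale = input_scale, state_scale = state_scale,
                 x0 = x0),
            class = "reference_spec")
}

#' Linear decaying oscillator derivative
#' @param x State 2-vector.
#' @param u Input 2-vector.
#' @return dx/dt.
#' @export
linear_derivative <- function(x, u = c(0, 0)) {
  c(u[1] / 0.02 + (-0.2 * x[1] - x[2]) / 0.05,
    u[2] / 0.02 + (x[1] - 0.2 * x[2]) / 0.05)
}

#' van der Pol oscillator derivative
#' @inheritParams linear_derivative
#' @return dx/dt.
#' @export
vdp_derivative <- function(x, u = c(0, 0)) {
  c(u[1] / 0.02 + x[2] / 0.125,
    u[2] / 0.02 + (2 * (1 - x[1]^2) * x[2] - x[1]) / 0.125)
}

#' Lorenz system derivative (shifted third coordinate)
#'
#' The classic Lorenz system with `x3 = Z - 28`, so the observables vary
#' around zero; the shifted equilibrium of the unforced flow is
#' `(0, 0, -28)`.
#' @param x State 3-vector.
#' @param u Input 3-vector.
#' @return dx/dt.
#' @export
lorenz_derivative <- function(x, u = c(0, 0, 0)) {
  c(u[1] / 0.02 + 10 * (x[2] - x[1]),
    u[2] / 0.02 - x[1] * x[3] - x[2],
    u[3] / 0.02 + x[1] * x[2] - 8 * (x[3] + 28) / 3)
}

#' Linear system with a non-linear input transform
#'
#' The linear decaying oscillator driven through the odd non-linearity
#' `g(u) = 10 * ((u/0.1)^3 - u/0.4)` applied componentwise.
#' @inheritParams linear_derivative
#' @return dx/dt.
#' @export
ff_nonlinear_derivative <- function(x, u = c(0, 0)) {
  g <- 10 * ((u / 0.1)^3 - u / 0.4)
  c(g[1] + (-0.2 * x[1] - x[2]) / 0.05,
    g[2] + (x[1] - 0.2 * x[2]) / 0.05)
}

#' Effective torque with soft joint limits
#'
#' To keep the arm joints from rotating through 360 degrees, a fraction of
#' the applied torque is subtracted when a joint moves past 90 degrees in
#' the direction of the torque: the fraction rises linearly from 0 at
#' `pi/2` to 1 at `3*pi/4`, fully cancelling the torque beyond. Continuous
#' in the angle and odd under `(u, theta) -> (-u, -theta)`.
#'
#' @param u Input torque 2-vector.
#' @param theta Joint angle 2-vector (rad).
#' @return Effective torque 2-vector.
#' @export
torque_clip <- function(u, theta) {
  sig <- function(th) pmin(pmax((th - pi / 2) / (pi / 4), 0), 1)
  ifelse(u == 0, 0, ifelse(u > 0, u - u * sig(theta), u - u * sig(-theta)))
}

#' Two-link arm derivative
#'
#' Rigid-body dynamics of the two-link arm under gravity:
#' `dtheta/dt = omega` and
#' `domega/dt = M(theta)^-1 (tau - C(theta, omega) - B omega - g D(theta))`
#' with inertia matrix `M`, centripetal/Coriolis vector `C`, damping `B`
#' and gravity vector `D`; `tau` is the clipped torque from
#' [torque_clip()].
#'
#' @param theta Joint angles (rad), 2-vector.
#' @param omega Angular velocities (rad/s), 2-vector.
#' @param u Input torques (N m), 2-vector.
#' @param params An [arm_params()].
#' @return A list with `dtheta` and `domega`.
#' @export
arm_derivative <- function(theta, omega, u = c(0, 0), params = arm_params()) {
  p <- params
  d1 <- p$I1 + p$I2 + p$m2 * p$l1^2
  d2 <- p$m2 * p$l1 * p$s2
  d3 <- p$I2
  c2 <- cos(theta[2]); s2 <- sin(theta[2])
  M <- matrix(c(d1 + 2 * d2 * c2 + p$m1 * p$s1^2 + p$m2 * p$s2^2,
                d3 + d2 * c2 + p$m2 * p$s2^2,
                d3 + d2 * c2 + p$m2 * p$s2^2,
                d3 + p$m2 * p$s2^2), 2, 2)
  C <- c(-omega[2] * (2 * omega[1] + omega[2]),
         omega[1]^2) * d2 * s2
  B <- matrix(c(p$b11, p$b21, p$b12, p$b22), 2, 2)
  D <- c((p$m1 * p$s1 + p$m2 * p$l1) * sin(theta[1]) +
           p$m2 * p$s2 * sin(theta[1] + theta[2]),
         p$m2 * p$s2 * sin(theta[1] + theta[2]))
  tau <- torque_clip(u, theta)
  if (abs(det(M)) < .Machine$double.eps)
    stop("singular inertia matrix")
  list(dtheta = omega,
       domega = drop(solve(M, tau - C - drop(B %*% omega) - p$g * D)))
}

#' Derivative of a reference system in raw units
#'
#' Dispatch helper used by the pure-R oracle paths.
#' @param spec A [reference_spec()].
#' @param x Raw state vector.
#' @param u Raw input vector.
#' @return dx/dt in raw units.
#' @export
reference_derivative <- function(spec, x, u) {
  switch(spec$system,
         linear = linear_derivative(x, u),
         vanderpol = vdp_derivative(x, u),
         lorenz = lorenz_derivative(x, u),
         ff_nonlinear = ff_nonlinear_derivative(x, u),
         arm = {
           d <- arm_derivative(x[1:2], x[3:4], u, spec$params)
           c(d$dtheta, d$domega)
         })
}

#' Integrate a reference system
#'
#' Forward-Euler integration at the network time step. The input `u` is in
#' raw units (torques for the arm, network units otherwise); the returned
#' trajectory is in network units, i.e. for the arm the 4-vector
#' `(theta1, theta2, omega1, omega2)` with the dimensionless scalings
#' applied. Row `t` is the state after step `t`.
#'
#' @param spec A [reference_spec()].
#' @param u A `steps x nc` input matrix in raw units.
#' @param dt Time step in seconds.
#' @param x0 Optional initial state in raw units.
#' @param n_substeps Euler sub-steps per network step (the input is held
#'   constant within a step). The default 10 keeps the integration stable
#'   through the stiff excursions of the driven van der Pol system; set
#'   to 1 for a plain single-step Euler scheme.
#' @return A `steps x nd` state matrix in network units.
#' @export
integrate_reference <- function(spec, u, dt, x0 = NULL, n_substeps = 10L) {
  stopifnot(inherits(spec, "reference_spec"), is.matrix(u),
            ncol(u) == spec$nc, dt > 0, n_substeps >= 1)
  if (is.null(x0)) x0 <- spec$x0
  pars <- if (spec$system == "arm") arm_par_vec(spec$params) else numeric(0)
  x <- cpp_integrate_reference(spec$code, t(u), x0, dt, pars,
                               as.integer(n_substeps))
  if (spec$system == "arm") {
    # state rows already (th1, th2, om1, om2); apply network scalings
    x <- x * spec$state_scale
  }
  t(x)
}

#' Low-pass filter a reference trajectory
#'
#' Applies the synaptic filter kernel `exp(-t/tau)/tau` columnwise (exact
#' exponential update, unit DC gain), as used for the error node when
#' reference filtering is on.
#' @param x A `steps x d` matrix.
#' @param tau Filter time constant (s).
#' @param dt Time step (s).
#' @param init Initial trace (recycled over columns).
#' @return The filtered matrix.
#' @export
filter_series <- function(x, tau, dt, init = 0) {
  decay <- exp(-dt / tau)
  init <- rep_len(init, ncol(x))
  out <- x
  for (j in seq_len(ncol(x)))
    out[, j] <- stats::filter(x[, j] * (1 - decay), decay,
                              method = "recursive", init = init[j])
  out
}
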