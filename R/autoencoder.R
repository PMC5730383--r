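#' Solve readout decoders by ridge regression
#'
#' Computes linear readout weights that, together with the ensemble's fixed
#' encoders, form an auto-encoder around the population: a static point
#' fed in through the encoders and decoded back from the static rates
#' returns (approximately) the point itself. `n_samples` points are drawn
#' volume-uniformly from the ball of radius `ensemble$radius`, the static
#' rates `A` (samples x neurons) are evaluated, and the decoders minimise
#' the squared reconstruction error with an L2 penalty
#' `lambda = n_samples * (0.1 * max(A))^2`. The feedback gain `k` is not
#' folded into the decoders; it is applied separately in the feedback path.
#'
#' @param ensemble A [sample_tuning()] ensemble.
#' @param n_samples Number of regression samples `P` (default: one per
#'   neuron).
#' @param lambda_reg Optional override of the ridge coefficient.
#' @return A `decoder_solve` with `decoders` (`dim x n_neurons`),
#'   `lambda_reg`, `n_samples`, `sample_radius`.
#' @export
solve_decoders <- function(ensemble, n_samples = ensemble$n_neurons,
                           lambda_reg = NULL) {
  stopifnot(n_samples >= ensemble$dim)
  pts <- sample_ball(n_samples, ensemble$dim, ensemble$radius)
  A <- static_rates(ensemble, pts)
  if (max(A) <= 0)
    stop("degenerate tuning: all sampled activities are zero")
  if (is.null(lambda_reg)) lambda_reg <- n_samples * (0.1 * max(A))^2
  stopifnot(lambda_reg > 0)
  G <- crossprod(A)
  diag(G) <- diag(G) + lambda_reg
  d <- solve(G, crossprod(A, pts))        # n_neurons x dim
  structure(list(decoders = t(d), lambda_reg = lambda_reg,
                 n_samples = n_samples, sample_radius = ensemble$radius),
            class = "decoder_solve")
}

#' Uniform samples from a ball
#'
#' Volume-uniform points in the `dim`-ball of given radius: directions
#' uniform on the sphere, radii proportional to `U^(1/dim)`.
#' @param n Number of points.
#' @param dim Dimensionality.
#' @param radius Ball radius.
#' @return An `n x dim` matrix.
#' @export
sample_ball <- function(n, dim, radius) {
  z <- matrix(rnorm(n * dim), n, dim)
  z <- z / sqrt(rowSums(z^2))
  z * (radius * runif(n)^(1 / dim))
}

#' Round-trip accuracy of the encoder/decoder loop
#'
#' For random points in the representation ball, compares
#' `k * decoders %*% static_rates(point)` with `k * point` and summarises
#' the relative reconstruction errors.
#'
#' @param ensemble A [sample_tuning()] ensemble.
#' @param decoders A `dim x n_neurons` decoder matrix (or a
#'   [solve_decoders()] result).
#' @param k Loop gain.
#' @param n_test Number of random test points.
#' @return A list with `mean_rel_error`, `median_rel_error`, per-point
#'   `rel_errors`, and the absolute `origin_error` at the zero vector.
#' @export
roundtrip_check <- function(ensemble, decoders, k = 1, n_test = 100) {
  if (inherits(decoders, "decoder_solve")) decoders <- decoders$decoders
  pts <- sample_ball(n_test, ensemble$dim, ensemble$radius)
  A <- static_rates(ensemble, pts)              # n_test x N
  dec <- k * tcrossprod(A, decoders)            # n_test x dim
  err <- sqrt(rowSums((dec - k * pts)^2))
  nrm <- k * sqrt(rowSums(pts^2))
  rel <- err / nrm
  origin <- sqrt(sum((k * drop(decoders %*% static_rates(ensemble,
                                                         numeric(ensemble$dim))))^2))
  list(mean_rel_error = mean(rel), median_rel_error = median(rel),
       rel_errors = rel, origin_error = origin)
}
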