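#' Default network and protocol parameters per reference system
#'
#' Returns the shipped defaults for one of the five reference systems:
#' numbers of neurons per layer, representation radii `r1` (command) and
#' `r2` (state), babbling amplitudes `zeta1` (fast pulse) and `zeta2`
#' (pedestal), pedestal period, learning rate, and flags. Amplitudes are
#' in raw input units (torques for the arm). Override any field through
#' `...`.
#'
#' @param system Reference system name.
#' @param ... Named overrides of individual fields.
#' @return A named list (class `follow_config`).
#' @export
follow_config <- function(system = c("vanderpol", "linear", "lorenz",
                                     "ff_nonlinear", "arm"), ...) {
  system <- match.arg(system)
  cfg <- switch(system,
    linear = list(n_neurons = 2000, t_period = 2, r1 = 0.2, r2 = 1,
                  zeta1 = 0.2 / 6, zeta2 = 1 / 16),
    # pulses per component; pedestal only on the velocity component --
    # a sustained offset on the position component would make the driven
    # oscillator drift without bound (see the methods vignette)
    vanderpol = list(n_neurons = 3000, t_period = 4, r1 = 0.2, r2 = 5,
                     zeta1 = c(0.2 / 6, 0.2 / 2), zeta2 = c(0, 0.2 / 2)),
    lorenz = list(n_neurons = 5000, t_period = 20, r1 = 6, r2 = 30,
                  zeta1 = 30 / 10, zeta2 = 0),
    ff_nonlinear = list(n_neurons = 2000, t_period = 2, r1 = 0.2, r2 = 1,
                        zeta1 = 0.2 / 0.6, zeta2 = 1 / 1.6),
    arm = list(n_neurons = 5000, t_period = 1, r1 = 0.2, r2 = 1,
               zeta1 = 1 / 0.3, zeta2 = 1 / 0.3))
  cfg$system <- system
  cfg$eta <- 2e-4
  cfg$k <- 10
  cfg$tau_s <- 0.020
  cfg$tau_eps <- 0.200
  cfg$scheme <- "intercept_maxrate"
  cfg$pulse_interval <- 0.050
  cfg$interpolate <- system == "arm"
  cfg$filter_reference <- system != "arm"
  cfg$dt <- 1e-3
  over <- list(...)
  bad <- setdiff(names(over), c(names(cfg), "n_cmd"))
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  validate_config(cfg)
  structure(cfg, class = "follow_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_neurons >= 1, r1 > 0, r2 > 0, all(zeta1 >= 0),
              all(zeta2 >= 0), t_period >= pulse_interval,
              eta >= 0, k >= 0, tau_s > 0, tau_eps > 0, dt > 0)
  })
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' The file must contain a `system` field; all other fields override the
#' [follow_config()] defaults for that system. Unknown fields are
#' rejected with an exhaustive list.
#'
#' @param path Path to a YAML file.
#' @return A validated `follow_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$system)) stop("config must name a 'system'")
  sys <- raw$system
  raw$system <- NULL
  raw <- lapply(raw, function(v) if (is.list(v)) unlist(v) else v)
  do.call(follow_config, c(list(system = sys), raw))
}

#' Save a fitted model to a run directory
#'
#' Writes the configuration (YAML), the weight and decoder arrays (RDS,
#' the R named-array container), the learning-curve metrics (tab-delimited
#' text) and a manifest listing every artifact with its MD5 checksum.
#'
#' @param fit A [follow()] fit.
#' @param dir Output directory (created if needed).
#' @return The manifest as a data frame, invisibly.
#' @export
save_run <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- fit$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  arrays <- list(w_ff = fit$net$w_ff, w_rec = fit$net$w_rec,
                 decoders = fit$net$decoders,
                 fb_encoders = fit$net$fb_encoders,
                 gains_cmd = fit$net$cmd$gains, biases_cmd = fit$net$cmd$biases,
                 encoders_cmd = fit$net$cmd$encoders,
                 gains_rec = fit$net$rec$gains, biases_rec = fit$net$rec$biases,
                 encoders_rec = fit$net$rec$encoders,
                 mask_ff = fit$net$mask_ff, mask_rec = fit$net$mask_rec,
                 radius_cmd = fit$net$cmd$radius, radius_rec = fit$net$rec$radius,
                 scheme = fit$net$cmd$scheme, seed = fit$seed)
  saveRDS(arrays, file.path(dir, "arrays.rds"))
  metrics <- data.frame(block_start_s = fit$block_times,
                        block_mse = fit$block_mse)
  utils::write.table(metrics, file.path(dir, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c("config.yaml", "arrays.rds", "metrics.tsv")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- data.frame(file = files, md5 = unname(sums))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Load a saved run, verifying checksums
#'
#' Refuses to load when any artifact's MD5 checksum disagrees with the
#' manifest.
#' @param dir A directory written by [save_run()].
#' @return A list with `config`, `arrays` and `metrics`.
#' @export
load_run <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  sums <- tools::md5sum(file.path(dir, manifest$file))
  bad <- manifest$file[unname(sums) != manifest$md5]
  if (length(bad))
    stop("checksum mismatch, refusing to load: ", paste(bad, collapse = ", "))
  list(config = load_config(file.path(dir, "config.yaml")),
       arrays = readRDS(file.path(dir, "arrays.rds")),
       metrics = utils::read.table(file.path(dir, "metrics.tsv"), sep = "\t",
                                   header = TRUE))
}

# One user seed expands deterministically into the per-component seeds
# (tuning/decoders, babbling input, noise, test input).
expand_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("tuning", "input", "noise", "test")
  s
}
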