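# Stochastic view augmentation of multispectral voxel signatures.  The five
# transforms simulate scanner/batch effects while preserving tissue
# identity, and are applied in a fixed order: (i) global multiplicative/
# additive intensity shift, (ii) smooth low-rank per-channel gain (Legendre
# polynomials over the channel index), (iii) monotone gamma-like intensity
# warp, (iv) additive Gaussian noise, (v) random feature dropout.  Every
# magnitude scales linearly with a `strength` in [0, 1] that is ramped up
# over training.

#' Augmentation configuration
#'
#' Magnitudes are mild, scanner-plausible defaults; all scale with the
#' per-step `strength`.
#'
#' @param global_gain_range half-width of the uniform global multiplicative
#'   shift (0.1 = +/-10 percent at full strength).
#' @param global_offset_sd standard deviation of the global additive shift.
#' @param lowrank_rank number of Legendre components of the smooth
#'   per-channel gain.
#' @param lowrank_amplitude standard deviation of each Legendre coefficient
#'   at full strength.
#' @param gamma_log_range half-width of the uniform log-gamma exponent for
#'   the monotone intensity warp.
#' @param noise_sd additive Gaussian noise standard deviation at full
#'   strength.
#' @param dropout_rate per-entry zeroing probability at full strength.
#' @param ramp_start strength at step 0 of the linear ramp (reaches 1 at the
#'   final step).
#' @param ramp_shape `"linear"` or `"constant"` (constant holds strength at
#'   1 throughout).
#' @return a list of class `augmentation_config`.
#' @export
augmentation_config <- function(global_gain_range = 0.10,
                                global_offset_sd = 0.05,
                                lowrank_rank = 3L,
                                lowrank_amplitude = 0.05,
                                gamma_log_range = 0.2,
                                noise_sd = 0.1,
                                dropout_rate = 0.3,
                                ramp_start = 0.2,
                                ramp_shape = c("linear", "constant")) {
  ramp_shape <- match.arg(ramp_shape)
  cfg <- list(global_gain_range = global_gain_range,
              global_offset_sd = global_offset_sd,
              lowrank_rank = as.integer(lowrank_rank),
              lowrank_amplitude = lowrank_amplitude,
              gamma_log_range = gamma_log_range,
              noise_sd = noise_sd, dropout_rate = dropout_rate,
              ramp_start = ramp_start, ramp_shape = ramp_shape)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop_config("dropout_rate", "must be in [0, 1)")
  for (f in c("global_gain_range", "global_offset_sd", "lowrank_amplitude",
              "gamma_log_range", "noise_sd"))
    if (cfg[[f]] < 0) stop_config(f, "must be >= 0")
  if (cfg$ramp_start < 0 || cfg$ramp_start > 1)
    stop_config("ramp_start", "must be in [0, 1]")
  class(cfg) <- "augmentation_config"
  cfg
}

# Legendre polynomials P1..P3 on [-1, 1]
legendre <- function(x, r) {
  switch(r,
         x,
         (3 * x^2 - 1) / 2,
         (5 * x^3 - 3 * x) / 2,
         stop("Legendre order > 3 not supported", call. = FALSE))
}

#' Augmentation strength schedule
#'
#' Non-decreasing in `step`; equals the ramp start at step 0 and 1 at
#' `total_steps`.
#'
#' @param step current step (0-based, `0 <= step <= total_steps`).
#' @param total_steps total training steps (> 0).
#' @param config an [augmentation_config()].
#' @export
ramp_strength <- function(step, total_steps, config = augmentation_config()) {
  if (total_steps <= 0) stop("total_steps must be > 0", call. = FALSE)
  if (step < 0 || step > total_steps) stop("step out of range", call. = FALSE)
  if (config$ramp_shape == "constant") return(1)
  config$ramp_start + (1 - config$ramp_start) * step / total_steps
}

#' Produce one augmented view of a voxel batch
#'
#' Two calls with different seeds give two independent views of the same
#' batch (the positive pair of the contrastive loss).  At `strength = 0`
#' the input is returned unchanged.
#'
#' @param batch voxel-by-channel matrix.
#' @param strength scalar in `[0, 1]` scaling all magnitudes.
#' @param config an [augmentation_config()].
#' @param seed integer seed for this view's perturbation draw.
#' @return augmented matrix of the same shape.
#' @export
augment_view <- function(batch, strength, config = augmentation_config(),
                         seed = 1L) {
  X <- as.matrix(batch)
  check_finite(X, "batch")
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]", call. = FALSE)
  if (strength == 0) return(X)
  Fn <- ncol(X)
  with_seed(seed, {
    # (i) global multiplicative/additive shift
    m <- stats::runif(1, 1 - config$global_gain_range * strength,
                      1 + config$global_gain_range * strength)
    o <- stats::rnorm(1, 0, config$global_offset_sd * strength)
    X <- X * m + o
    # (ii) smooth low-rank per-channel gain
    if (config$lowrank_rank > 0 && config$lowrank_amplitude > 0) {
      u <- if (Fn > 1) seq(-1, 1, length.out = Fn) else 0
      g <- rep(1, Fn)
      for (r in seq_len(config$lowrank_rank)) {
        a_r <- stats::rnorm(1, 0, config$lowrank_amplitude * strength)
        g <- g + a_r * legendre(u, r)
      }
      X <- sweep(X, 2L, g, "*")
    }
    # (iii) monotone gamma-like warp on a batch-min-max normalized copy
    gam <- exp(stats::runif(1, -config$gamma_log_range, config$gamma_log_range) * strength)
    if (gam != 1) {
      mn <- min(X); mx <- max(X)
      if (mx > mn) X <- ((X - mn) / (mx - mn))^gam * (mx - mn) + mn
    }
    # (iv) additive Gaussian noise
    if (config$noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd * strength),
                      nrow(X), Fn)
    # (v) random feature dropout
    p <- config$dropout_rate * strength
    if (p > 0) X <- X * matrix(stats::runif(length(X)) >= p, nrow(X), Fn)
    X
  })
}
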