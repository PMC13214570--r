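# Feed-forward regressor from frozen embeddings to the standardized
# normative DaT target.  The architecture deliberately matches the
# adversarial heads (which cannot recover the suppressed biases) except for
# the scalar output layer; trained with mini-batch MSE, AdamW and a
# single-period cosine-annealing schedule.

#' Regressor configuration
#'
#' @param input_dim embedding dimension (16 for the main pipeline; the raw-
#'   feature ablation passes the full channel count).
#' @param hidden hidden-layer widths (default three layers matching the
#'   adversarial-head profile).
#' @param dropout dropout probability (default 0.3).
#' @param lr,weight_decay AdamW settings (defaults 1e-3, 1e-2).
#' @param batch_size voxels per mini-batch (default 4096).
#' @param epochs training epochs (default 30) with cosine annealing of the
#'   learning rate to 0 over all steps.
#' @param profile `"desk"` (512 -> 128-wide layers scaled down) or `"full"`.
#' @param seed integer seed.
#' @return list of class `regressor_config`.
#' @export
regressor_config <- function(input_dim = 16L, hidden = NULL, dropout = 0.3,
                             lr = 1e-3, weight_decay = 1e-2,
                             batch_size = 4096L, epochs = 30L,
                             profile = c("desk", "full"), seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") rep(512L, 3L) else rep(128L, 3L)
  cfg <- list(input_dim = as.integer(input_dim),
              hidden = as.integer(hidden %||% defaults),
              dropout = dropout, lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              profile = profile, seed = as.integer(seed))
  if (cfg$epochs < 1L) stop_config("epochs", "must be >= 1")
  if (cfg$batch_size < 1L) stop_config("batch_size", "must be >= 1")
  class(cfg) <- "regressor_config"
  cfg
}

#' Mean-squared-error loss
#'
#' @param pred,target numeric vectors (or single-column matrices).
#' @return scalar mean of squared differences.
#' @export
mse_loss <- function(pred, target) mean((as.numeric(pred) - as.numeric(target))^2)

#' Train the embedding-to-DaT regressor
#'
#' Minimizes mini-batch MSE between the network output and the standardized
#' atlas target with AdamW; the learning rate follows a single cosine-
#' annealing period from `lr` to 0 across all steps.  Deterministic given
#' `config$seed`.  A warning is raised if the targets do not look
#' standardized (|mean| > 0.1 or |var - 1| > 0.2).
#'
#' @param embeddings training `n x input_dim` matrix.
#' @param targets standardized atlas values, length `n`.
#' @param config a [regressor_config()].
#' @return object of class `dat_regressor` with the trained network, the
#'   per-step loss trace, and the config snapshot.
#' @export
train_regressor <- function(embeddings, targets, config = regressor_config()) {
  Z <- as.matrix(embeddings)
  y <- as.numeric(targets)
  check_finite(Z, "embeddings"); check_finite(y, "targets")
  if (nrow(Z) != length(y)) stop("embeddings/targets length mismatch", call. = FALSE)
  if (ncol(Z) != config$input_dim)
    stop(sprintf("embeddings have %d columns; config expects %d",
                 ncol(Z), config$input_dim), call. = FALSE)
  if (abs(mean(y)) > 0.1 || abs(stats::var(y) - 1) > 0.2)
    warning("targets do not appear standardized (mean 0, variance 1)")

  with_seed(derive_seed(config$seed, 31L), {
    net <- mlp_init(config$input_dim, config$hidden, 1L,
                    block_order = "ln_relu", dropout = config$dropout,
                    seed = derive_seed(config$seed, 32L))
    trainer <- .cpp_reg_trainer_create(net$layers, net$out, config$dropout,
                                       config$weight_decay)
    n <- nrow(Z)
    bs <- min(config$batch_size, n)
    steps_per_epoch <- max(1L, ceiling(n / bs))
    total <- config$epochs * steps_per_epoch
    trace <- numeric(total)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (k in seq_len(steps_per_epoch)) {
        step <- step + 1L
        rows <- ord[((k - 1L) * bs + 1L):min(k * bs, n)]
        lr_t <- lr_cosine(step, total, config$lr)
        drop_seed <- as.integer(floor(stats::runif(1) * 2147483647))
        loss <- .cpp_reg_trainer_step(trainer, Z[rows, , drop = FALSE],
                                      y[rows], lr_t, drop_seed)
        if (!is.finite(loss))
          stop(sprintf("non-finite regression loss at step %d", step), call. = FALSE)
        trace[step] <- loss
      }
    }
    fitted <- .cpp_reg_trainer_params(trainer)
    net$layers <- fitted$layers
    net$out <- fitted$out
    structure(list(net = net, trace = trace, config = config,
                   final_loss = trace[total], seed = config$seed),
              class = "dat_regressor")
  })
}

#' Predict standardized DaT values from embeddings
#'
#' @param object a `dat_regressor`.
#' @param embeddings `n x input_dim` matrix.
#' @param ... unused.
#' @return numeric vector of predictions on the standardized scale.
#' @export
predict.dat_regressor <- function(object, embeddings, ...) {
  drop(mlp_infer(object$net, as.matrix(embeddings)))
}

#' Predict DaT binding potential on the original atlas scale
#'
#' Applies the regressor and then inverts the atlas standardization.
#'
#' @param regressor a `dat_regressor`.
#' @param embeddings `n x input_dim` matrix.
#' @param atlas_stats the list returned by [standardize_atlas()].
#' @return predictions on the binding-potential scale.
#' @export
predict_dat <- function(regressor, embeddings, atlas_stats) {
  if (is.null(atlas_stats$mean) || is.null(atlas_stats$sd))
    stop("missing atlas standardization stats", call. = FALSE)
  invert_atlas(predict(regressor, embeddings), atlas_stats)
}

#' @export
print.dat_regressor <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("DaT regressor: %d -> %s -> 1, %d epochs, batch %d, cosine-annealed AdamW\n",
              cfg$input_dim, paste(cfg$hidden, collapse = "/"),
              cfg$epochs, cfg$batch_size))
  cat(sprintf("  final training MSE: %.4f\n", x$final_loss))
  invisible(x)
}
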