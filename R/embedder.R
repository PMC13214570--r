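# Contrastive voxel embedder.  An MLP encoder maps (augmented) multispectral
# signatures to L2-normalized 16-D embeddings trained with a temperature-
# scaled InfoNCE loss; adversarial coordinate and subject heads, attached
# through a gradient-reversal layer (identity forward, gradient negation
# backward), force the encoder to hide voxel location and subject identity.
# Total loss: L = L_contrastive + w_c * L_coordinate + w_s * L_subject.

#' Encoder/training configuration for the contrastive embedder
#'
#' The `"full"` profile uses the reference settings (4 hidden layers of
#' 2048, heads of 3 x 512, batch 16384, 4000 steps); the `"desk"` profile
#' is a documented scaled-down variant for interactive and test use.
#' Any field can be overridden explicitly.
#'
#' @param input_dim feature dimension F.
#' @param embed_dim embedding dimension (default 16).
#' @param hidden encoder hidden-layer widths.
#' @param head_hidden adversarial-head hidden-layer widths.
#' @param dropout dropout probability (default 0.3).
#' @param temperature InfoNCE temperature tau (default 0.07).
#' @param w_coord,w_subject adversarial loss weights (default 20, 20).
#' @param coord_bins empirical-quantile bins per coordinate axis (default 16).
#' @param grl_lambda gradient-reversal scale (default 1).
#' @param steps,batch_size training steps and voxels per batch (each batch
#'   yields `2 * batch_size` augmented views).
#' @param lr,weight_decay AdamW learning rate and decoupled weight decay.
#' @param profile `"desk"` or `"full"`; sets defaults for `hidden`,
#'   `head_hidden`, `steps`, `batch_size` when those are `NULL`.
#' @param seed integer seed governing initialization, batching, dropout and
#'   augmentation streams.
#' @return a list of class `embedder_config`.
#' @export
embedder_config <- function(input_dim, embed_dim = 16L,
                            hidden = NULL, head_hidden = NULL,
                            dropout = 0.3, temperature = 0.07,
                            w_coord = 20, w_subject = 20,
                            coord_bins = 16L, grl_lambda = 1,
                            steps = NULL, batch_size = NULL,
                            lr = 1e-4, weight_decay = 1e-2,
                            profile = c("desk", "full"), seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full")
    list(hidden = rep(2048L, 4L), head_hidden = rep(512L, 3L),
         steps = 4000L, batch_size = 16384L)
  else
    list(hidden = rep(256L, 4L), head_hidden = rep(256L, 3L),
         steps = 500L, batch_size = 1024L)
  cfg <- list(input_dim = as.integer(input_dim), embed_dim = as.integer(embed_dim),
              hidden = as.integer(hidden %||% defaults$hidden),
              head_hidden = as.integer(head_hidden %||% defaults$head_hidden),
              dropout = dropout, temperature = temperature,
              w_coord = w_coord, w_subject = w_subject,
              coord_bins = as.integer(coord_bins), grl_lambda = grl_lambda,
              steps = as.integer(steps %||% defaults$steps),
              batch_size = as.integer(batch_size %||% defaults$batch_size),
              lr = lr, weight_decay = weight_decay,
              profile = profile, seed = as.integer(seed))
  if (cfg$temperature <= 0) stop_config("temperature", "must be > 0")
  if (cfg$embed_dim < 2L) stop_config("embed_dim", "must be >= 2")
  if (cfg$coord_bins < 2L) stop_config("coord_bins", "must be >= 2")
  if (cfg$steps < 1L) stop_config("steps", "must be >= 1")
  if (cfg$batch_size < 2L) stop_config("batch_size", "must be >= 2")
  class(cfg) <- "embedder_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## -- InfoNCE ---------------------------------------------------------------

# loss + gradient w.r.t. the stacked embeddings; rows 1..N of `Z` pair with
# rows N+1..2N.  Negatives are all 2N-1 other rows (both views, self
# excluded).  Delegates to the compiled kernel; the `_ref` version is the
# pure-R reference the tests compare against.
info_nce_grad <- function(Z, tau) {
  n2 <- nrow(Z)
  if (n2 %% 2L != 0L || n2 < 4L)
    stop("need an even number (>= 4) of stacked embeddings", call. = FALSE)
  .cpp_infonce_grad(Z, tau)
}

info_nce_grad_ref <- function(Z, tau) {
  n2 <- nrow(Z)
  if (n2 %% 2L != 0L || n2 < 4L)
    stop("need an even number (>= 4) of stacked embeddings", call. = FALSE)
  N <- n2 %/% 2L
  S <- tcrossprod(Z) / tau
  pos <- c(seq_len(N) + N, seq_len(N))
  # rows of Z are unit vectors, so S <= 1/tau: shifting by that constant is
  # enough for a stable exp without a per-row max scan
  mx <- 1 / tau
  E <- exp(S - mx)
  diag(E) <- 0                            # self-similarity excluded
  ssum <- rowSums(E)
  P <- E / ssum
  idx <- cbind(seq_len(n2), pos)
  loss <- mean(log(ssum) + mx - S[idx])
  G <- P
  G[idx] <- G[idx] - 1
  G <- G / n2
  dZ <- (G %*% Z + crossprod(G, Z)) / tau
  list(loss = loss, dZ = dZ)
}

#' Temperature-scaled InfoNCE loss of two embedding views
#'
#' For each of the `2N` stacked samples the positive is its paired view and
#' the denominator runs over all `2N - 1` other samples (both views, self
#' excluded); similarity is cosine (rows are unit-normalized internally if
#' needed).
#'
#' @param view1,view2 `N x d` embedding matrices, row i of each forming a
#'   positive pair.
#' @param temperature tau > 0.
#' @return scalar loss (mean over the `2N` samples).
#' @export
info_nce <- function(view1, view2, temperature = 0.07) {
  view1 <- as.matrix(view1); view2 <- as.matrix(view2)
  if (!all(dim(view1) == dim(view2)))
    stop("view shapes differ", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  Z <- l2_normalize(rbind(view1, view2))$Z
  info_nce_grad(Z, temperature)$loss
}

## -- coordinate discretization ---------------------------------------------

#' Build per-axis empirical-quantile bin edges from training coordinates
#'
#' Axes are first affinely normalized to `[0, 1]` over the pooled training
#' bounding box; interior edges are midpoints between consecutive order
#' statistics at the quantile cut positions, so on the training set every
#' bin holds its quantile share of voxels (within +/-1, ties aside).
#'
#' @param coords training voxel-by-3 coordinate matrix.
#' @param n_bins bins per axis (default 16).
#' @return object of class `coord_bins` with the bounding box and the
#'   `n_bins + 1` edges per axis.
#' @export
coord_bin_edges <- function(coords, n_bins = 16L) {
  coords <- as.matrix(coords)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop_config("n_bins", "must be >= 2")
  bbox <- apply(coords, 2L, range)
  edges <- vector("list", 3L)
  for (a in 1:3) {
    v <- (coords[, a] - bbox[1, a]) / max(bbox[2, a] - bbox[1, a], 1e-12)
    sv <- sort(v)
    n <- length(sv)
    pos <- ceiling(n * seq_len(n_bins - 1L) / n_bins)
    interior <- (sv[pos] + sv[pmin(pos + 1L, n)]) / 2
    edges[[a]] <- c(0, interior, 1)
  }
  structure(list(bbox = bbox, edges = edges, n_bins = n_bins),
            class = "coord_bins")
}

#' Discretize coordinates into per-axis quantile-bin labels
#'
#' Out-of-range coordinates clamp to the end bins.
#'
#' @param coords voxel-by-3 coordinate matrix.
#' @param bins a [coord_bin_edges()] object.
#' @return integer matrix of labels in `1..n_bins`, one column per axis.
#' @export
discretize_coords <- function(coords, bins) {
  coords <- as.matrix(coords)
  lab <- matrix(0L, nrow(coords), 3L)
  for (a in 1:3) {
    e <- bins$edges[[a]]
    if (is.unsorted(e)) stop("non-monotone bin edges", call. = FALSE)
    v <- (coords[, a] - bins$bbox[1, a]) /
      max(bins$bbox[2, a] - bins$bbox[1, a], 1e-12)
    l <- findInterval(v, e[2:bins$n_bins]) + 1L
    lab[, a] <- pmin(pmax(l, 1L), bins$n_bins)
  }
  colnames(lab) <- c("x", "y", "z")
  lab
}

## -- adversarial losses ----------------------------------------------------

# coordinate CE averaged over the three axes; returns loss and gradient
# w.r.t. the stacked logits (n x 3*n_bins)
coord_ce <- function(logits, labels, n_bins) {
  loss <- 0
  G <- logits * 0
  for (a in 1:3) {
    cols <- ((a - 1L) * n_bins + 1L):(a * n_bins)
    ce <- softmax_ce(logits[, cols, drop = FALSE], labels[, a])
    loss <- loss + ce$loss / 3
    G[, cols] <- ce$grad / 3
  }
  list(loss = loss, grad = G)
}

#' Adversarial head losses on a set of embeddings
#'
#' Standard cross-entropy of the coordinate head (averaged over the x, y, z
#' axes) and the subject head, evaluated in inference mode (no dropout).
#'
#' @param embeddings `n x d` embedding matrix.
#' @param coord_labels integer `n x 3` axis-bin labels.
#' @param subject_labels integer vector in `1..C_subject`.
#' @param coord_head,subject_head `dat_mlp` heads (coordinate head output
#'   dimension must be `3 * n_bins`).
#' @param n_bins coordinate bins per axis.
#' @return list with `coordinate` and `subject` losses.
#' @export
adversarial_losses <- function(embeddings, coord_labels, subject_labels,
                               coord_head, subject_head, n_bins) {
  lc <- coord_ce(mlp_forward(coord_head, embeddings)$out,
                 coord_labels, n_bins)$loss
  ls <- softmax_ce(mlp_forward(subject_head, embeddings)$out,
                   as.integer(subject_labels))$loss
  list(coordinate = lc, subject = ls)
}

## -- gradient-reversal diagnostic ------------------------------------------

# Encoder-parameter gradient of w * head_loss with or without the reversal
# layer, in deterministic (no-dropout) mode.  With `reversed = TRUE` the
# head gradient is multiplied by -lambda where it enters the encoder; the
# head's own parameters always receive the unreversed gradient.
grl_encoder_gradient <- function(encoder, head, X, labels, n_bins = NULL,
                                 w = 1, lambda = 1, reversed = TRUE) {
  fwd <- mlp_forward(encoder, X, training = FALSE)
  nr <- l2_normalize(fwd$out)
  hf <- mlp_forward(head, nr$Z, training = FALSE)
  if (!is.null(n_bins)) {
    ce <- coord_ce(hf$out, labels, n_bins)
  } else {
    ce <- softmax_ce(hf$out, as.integer(labels))
  }
  hb <- mlp_backward(head, hf, w * ce$grad)
  dZ <- hb$d_input
  if (reversed) dZ <- -lambda * dZ
  dU <- l2_normalize_backward(dZ, nr$Z, nr$nrm)
  eb <- mlp_backward(encoder, fwd, dU)
  list(loss = ce$loss, grads = grads_flat(eb, encoder))
}

## -- training ---------------------------------------------------------------

#' Train the contrastive embedder with adversarial bias removal
#'
#' Each step samples a voxel batch from the training subjects, produces two
#' independently augmented views, embeds them, and minimizes
#' `L_contrastive + w_c L_coordinate + w_s L_subject` with AdamW, where the
#' adversarial-head gradients reach the encoder sign-flipped (scaled by
#' `-grl_lambda`) while the heads themselves descend their own losses.
#' After training the heads are discarded and the encoder is frozen.
#'
#' @param features training voxel-by-channel matrix (preprocessed).
#' @param coords matching voxel-by-3 coordinates.
#' @param subject_id subject identifier per voxel (>= 2 distinct).
#' @param config an [embedder_config()].
#' @param aug_config an [augmentation_config()].
#' @param keep_heads retain the trained adversarial heads in the result
#'   (default `FALSE`, mirroring their post-training discard).
#' @return an object of class `dat_embedder` with the frozen encoder, the
#'   coordinate-bin edges, per-step loss traces, and the config snapshot.
#' @export
train_embedder <- function(features, coords, subject_id,
                           config, aug_config = augmentation_config(),
                           keep_heads = FALSE) {
  X <- as.matrix(features)
  coords <- as.matrix(coords)
  check_finite(X, "features")
  if (ncol(X) != config$input_dim)
    stop(sprintf("features have %d channels; config expects %d",
                 ncol(X), config$input_dim), call. = FALSE)
  subj <- factor(subject_id)
  n_subj <- nlevels(subj)
  if (n_subj < 2L)
    stop("need >= 2 training subjects (subject head degenerate otherwise)",
         call. = FALSE)
  nb <- config$coord_bins
  bins <- coord_bin_edges(coords, nb)
  labels <- discretize_coords(coords, bins)
  subj_int <- as.integer(subj)
  V <- nrow(X)

  with_seed(derive_seed(config$seed, 1L), {
    enc <- mlp_init(config$input_dim, config$hidden, config$embed_dim,
                    block_order = "relu_ln", dropout = config$dropout,
                    seed = derive_seed(config$seed, 2L))
    # heads use the listed order: linear -> layer norm -> ReLU -> dropout
    ch <- mlp_init(config$embed_dim, config$head_hidden, 3L * nb,
                   block_order = "ln_relu", dropout = config$dropout,
                   seed = derive_seed(config$seed, 3L))
    sh <- mlp_init(config$embed_dim, config$head_hidden, n_subj,
                   block_order = "ln_relu", dropout = config$dropout,
                   seed = derive_seed(config$seed, 4L))
    trainer <- .cpp_emb_trainer_create(enc$layers, enc$out, ch$layers, ch$out,
                                       sh$layers, sh$out, config$dropout,
                                       config$temperature, config$w_coord,
                                       config$w_subject, config$grl_lambda,
                                       config$lr, config$weight_decay, nb)
    traces <- matrix(NA_real_, config$steps, 3L,
                     dimnames = list(NULL, c("contrastive", "coordinate", "subject")))
    N <- config$batch_size
    for (step in seq_len(config$steps)) {
      idx <- sample.int(V, N, replace = TRUE)
      s <- ramp_strength(step, config$steps, aug_config)
      v1 <- augment_view(X[idx, , drop = FALSE], s, aug_config,
                         seed = derive_seed(config$seed, step, 11L))
      v2 <- augment_view(X[idx, , drop = FALSE], s, aug_config,
                         seed = derive_seed(config$seed, step, 22L))
      Xb <- rbind(v1, v2)
      lab_b <- labels[idx, , drop = FALSE][rep(seq_len(N), 2L), , drop = FALSE]
      sub_b <- rep(subj_int[idx], 2L)
      drop_seed <- as.integer(floor(stats::runif(1) * 2147483647))
      losses <- .cpp_emb_trainer_step(trainer, Xb, lab_b, sub_b, drop_seed)
      if (!all(is.finite(losses)))
        stop(sprintf("non-finite loss at step %d (contrastive=%g, coord=%g, subject=%g)",
                     step, losses[1], losses[2], losses[3]), call. = FALSE)
      traces[step, ] <- losses
    }
    fitted <- .cpp_emb_trainer_params(trainer)
    enc$layers <- fitted$encoder$layers
    enc$out <- fitted$encoder$out
    ch$layers <- fitted$coord_head$layers
    ch$out <- fitted$coord_head$out
    sh$layers <- fitted$subject_head$layers
    sh$out <- fitted$subject_head$out

    out <- structure(list(encoder = enc, bins = bins, traces = traces,
                          config = config, aug_config = aug_config,
                          subjects = levels(subj), seed = config$seed),
                     class = "dat_embedder")
    if (keep_heads) out$heads <- list(coordinate = ch, subject = sh)
    out
  })
}

#' Embed voxel signatures with a frozen encoder
#'
#' Inference mode (dropout disabled); every output row has unit Euclidean
#' norm.
#'
#' @param object a `dat_embedder`.
#' @param features voxel-by-channel matrix.
#' @param ... unused.
#' @return `n x embed_dim` embedding matrix.
#' @export
predict.dat_embedder <- function(object, features, ...) {
  X <- as.matrix(features)
  l2_normalize(mlp_infer(object$encoder, X))$Z
}

#' @rdname predict.dat_embedder
#' @param embedder a `dat_embedder`.
#' @export
encode <- function(embedder, features) predict(embedder, features)

#' @export
print.dat_embedder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("contrastive voxel embedder: %d -> %s -> %d (L2-normalized)\n",
              cfg$input_dim, paste(cfg$hidden, collapse = "/"), cfg$embed_dim))
  cat(sprintf("  tau=%.3g, w_coord=%g, w_subject=%g, %d bins/axis, %d steps, batch %d\n",
              cfg$temperature, cfg$w_coord, cfg$w_subject, cfg$coord_bins,
              cfg$steps, cfg$batch_size))
  k <- max(1L, nrow(x$traces) - 9L)
  fin <- colMeans(x$traces[k:nrow(x$traces), , drop = FALSE])
  cat(sprintf("  final losses (last 10 steps): contrastive %.3f, coordinate %.3f (chance %.3f), subject %.3f (chance %.3f)\n",
              fin[1], fin[2], log(cfg$coord_bins), fin[3], log(length(x$subjects))))
  invisible(x)
}

#' Save or restore a frozen embedder checkpoint
#'
#' The checkpoint holds the encoder parameters, coordinate-bin edges,
#' loss traces and the config snapshot in one file (R serialization).
#'
#' @param embedder a `dat_embedder`.
#' @param path checkpoint file path.
#' @export
save_embedder <- function(embedder, path) {
  stopifnot(inherits(embedder, "dat_embedder"))
  saveRDS(embedder, path)
  invisible(path)
}

#' @rdname save_embedder
#' @export
load_embedder <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "dat_embedder")) stop("not an embedder checkpoint", call. = FALSE)
  obj
}

#' Write per-step training-loss traces as TSV
#'
#' One row per training step with the contrastive, coordinate and subject
#' losses, for plotting loss curves.
#'
#' @param embedder a `dat_embedder`.
#' @param path output TSV path.
#' @export
write_loss_traces <- function(embedder, path) {
  df <- data.frame(step = seq_len(nrow(embedder$traces)), embedder$traces)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Linear subject-identity probe on frozen embeddings
#'
#' Fits a multinomial logistic classifier predicting subject identity from
#' embeddings and reports held-out accuracy: the diagnostic used to verify
#' that adversarial training removed subject information (accuracy near
#' chance) and that the no-adversarial ablation retains it.
#'
#' @param embeddings `n x d` matrix.
#' @param subject_id subject labels per row.
#' @param train_frac fraction of voxels (per subject) used for fitting.
#' @param seed split seed.
#' @return list with `accuracy`, `chance`, and the per-class counts.
#' @export
subject_probe <- function(embeddings, subject_id, train_frac = 0.5, seed = 1L) {
  y <- factor(subject_id)
  Z <- as.matrix(embeddings)
  with_seed(derive_seed(seed, 5L), {
    tr <- logical(length(y))
    for (lv in levels(y)) {
      rows <- which(y == lv)
      tr[sample(rows, max(1L, floor(train_frac * length(rows))))] <- TRUE
    }
    df <- data.frame(y = y, Z)
    fit <- nnet::multinom(y ~ ., data = df[tr, , drop = FALSE],
                          trace = FALSE, MaxNWts = 100000, maxit = 200)
    pred <- predict(fit, newdata = df[!tr, , drop = FALSE])
    list(accuracy = mean(pred == y[!tr]), chance = 1 / nlevels(y),
         n_test = sum(!tr))
  })
}
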