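# Minimal feed-forward network machinery (dense blocks with ReLU, layer
# normalization and inverted dropout), with hand-derived backward passes and
# a decoupled-weight-decay Adam optimizer.  All gradients are exact and are
# validated against finite differences in the test suite; the gradient-
# reversal contract of the adversarial heads builds on these primitives.

LN_EPS <- 1e-5

# column-broadcast helpers: add/multiply a length-d vector across the rows
# of an n x d matrix without sweep()'s aperm overhead
row_add <- function(A, b) A + rep(b, rep.int(nrow(A), length(b)))
row_mul <- function(A, b) A * rep(b, rep.int(nrow(A), length(b)))

layernorm_forward <- function(X, gamma, beta) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv                       # row-wise scaling
  Y <- row_add(row_mul(xhat, gamma), beta)
  list(Y = Y, xhat = xhat, inv = inv)
}

layernorm_backward <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- row_mul(dY, gamma)
  r1 <- rowMeans(dxhat)
  r2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - r1 - xhat * r2) * cache$inv
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

#' Initialize a dense multi-layer perceptron
#'
#' Hidden blocks are linear layers followed (in configurable order) by ReLU,
#' layer normalization, and dropout; the output layer is purely linear.
#' `block_order = "relu_ln"` applies ReLU before layer normalization (the
#' encoder convention here); `"ln_relu"` normalizes first (the head and
#' regressor convention).
#'
#' @param input_dim,output_dim integer layer widths.
#' @param hidden integer vector of hidden-layer widths.
#' @param block_order `"relu_ln"` or `"ln_relu"`.
#' @param dropout dropout probability in `[0, 1)` applied after each block.
#' @param seed integer seed for He-style weight initialization.
#' @return an object of class `dat_mlp`.
#' @keywords internal
mlp_init <- function(input_dim, hidden, output_dim,
                     block_order = c("relu_ln", "ln_relu"),
                     dropout = 0.3, seed = 1L) {
  block_order <- match.arg(block_order)
  if (dropout < 0 || dropout >= 1) stop_config("dropout", "must be in [0, 1)")
  with_seed(seed, {
    dims <- c(input_dim, hidden)
    layers <- vector("list", length(hidden))
    for (i in seq_along(hidden)) {
      fi <- dims[i]; fo <- dims[i + 1L]
      layers[[i]] <- list(
        W = matrix(stats::rnorm(fi * fo, 0, sqrt(2 / fi)), fi, fo),
        b = numeric(fo),
        gamma = rep(1, fo),
        beta = numeric(fo))
    }
    fi <- dims[length(dims)]
    out <- list(W = matrix(stats::rnorm(fi * output_dim, 0, sqrt(1 / fi)),
                           fi, output_dim),
                b = numeric(output_dim))
    structure(list(layers = layers, out = out, block_order = block_order,
                   dropout = dropout, input_dim = input_dim,
                   output_dim = output_dim),
              class = "dat_mlp")
  })
}

# Forward pass.  `training = TRUE` activates dropout, drawing masks from the
# current RNG stream (callers scope the stream with `with_seed`).  Delegates
# to the compiled kernel; `mlp_forward_ref` is the pure-R reference the
# tests compare against.
mlp_forward <- function(net, X, training = FALSE) {
  if (ncol(X) != net$input_dim)
    stop(sprintf("input has %d columns; network expects %d",
                 ncol(X), net$input_dim), call. = FALSE)
  rng_seed <- if (training && net$dropout > 0)
    as.integer(floor(stats::runif(1) * 2147483647)) else 0L
  .cpp_mlp_forward(X,
                   lapply(net$layers, `[[`, "W"),
                   lapply(net$layers, `[[`, "b"),
                   lapply(net$layers, `[[`, "gamma"),
                   lapply(net$layers, `[[`, "beta"),
                   net$out$W, net$out$b,
                   net$block_order == "relu_ln",
                   net$dropout, training, rng_seed)
}

# lean inference pass: same arithmetic as mlp_forward(training = FALSE)
# but no backward caches; used by the predict methods
mlp_infer <- function(net, X) {
  if (ncol(X) != net$input_dim)
    stop(sprintf("input has %d columns; network expects %d",
                 ncol(X), net$input_dim), call. = FALSE)
  .cpp_mlp_infer(X,
                 lapply(net$layers, `[[`, "W"),
                 lapply(net$layers, `[[`, "b"),
                 lapply(net$layers, `[[`, "gamma"),
                 lapply(net$layers, `[[`, "beta"),
                 net$out$W, net$out$b,
                 net$block_order == "relu_ln")
}

mlp_forward_ref <- function(net, X, training = FALSE) {
  if (ncol(X) != net$input_dim)
    stop(sprintf("input has %d columns; network expects %d",
                 ncol(X), net$input_dim), call. = FALSE)
  caches <- vector("list", length(net$layers))
  H <- X
  p <- net$dropout
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    A <- row_add(H %*% ly$W, ly$b)
    if (net$block_order == "relu_ln") {
      pos <- A > 0
      R <- A * pos
      ln <- layernorm_forward(R, ly$gamma, ly$beta)
      D <- ln$Y
    } else {
      ln <- layernorm_forward(A, ly$gamma, ly$beta)
      pos <- ln$Y > 0
      R <- ln$Y * pos
      D <- R
    }
    mask <- NULL
    if (training && p > 0) {
      mask <- matrix((stats::runif(length(D)) >= p) / (1 - p),
                     nrow(D), ncol(D))
      D <- D * mask
    }
    caches[[i]] <- list(X = H, pos = pos, xhat = ln$xhat, inv = ln$inv,
                        mask = mask)
    H <- D
  }
  out <- row_add(H %*% net$out$W, net$out$b)
  list(out = out, H_last = H, caches = caches)
}

# Backward pass: returns gradients w.r.t. every parameter plus the input.
mlp_backward <- function(net, fwd, d_out) {
  .cpp_mlp_backward(fwd,
                    lapply(net$layers, `[[`, "W"),
                    lapply(net$layers, `[[`, "gamma"),
                    net$out$W,
                    net$block_order == "relu_ln",
                    d_out)
}

mlp_backward_ref <- function(net, fwd, d_out) {
  grads <- list(out = list(W = crossprod(fwd$H_last, d_out),
                           b = colSums(d_out)),
                layers = vector("list", length(net$layers)))
  dH <- tcrossprod(d_out, net$out$W)
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ca <- fwd$caches[[i]]
    if (!is.null(ca$mask)) dH <- dH * ca$mask
    ln_cache <- list(xhat = ca$xhat, inv = ca$inv)
    if (net$block_order == "relu_ln") {
      lb <- layernorm_backward(dH, ln_cache, ly$gamma)
      dA <- lb$dX * ca$pos
    } else {
      dR <- dH * ca$pos
      lb <- layernorm_backward(dR, ln_cache, ly$gamma)
      dA <- lb$dX
    }
    grads$layers[[i]] <- list(W = crossprod(ca$X, dA), b = colSums(dA),
                              gamma = lb$dgamma, beta = lb$dbeta)
    dH <- tcrossprod(dA, ly$W)
  }
  grads$d_input <- dH
  grads
}

## -- parameter flattening (for the optimizer and for gradient checks) ------

net_params <- function(net) {
  ps <- list()
  for (i in seq_along(net$layers))
    for (nm in c("W", "b", "gamma", "beta"))
      ps[[paste0("l", i, ".", nm)]] <- net$layers[[i]][[nm]]
  ps[["out.W"]] <- net$out$W
  ps[["out.b"]] <- net$out$b
  ps
}

net_set_params <- function(net, ps) {
  for (i in seq_along(net$layers))
    for (nm in c("W", "b", "gamma", "beta"))
      net$layers[[i]][[nm]] <- ps[[paste0("l", i, ".", nm)]]
  net$out$W <- ps[["out.W"]]
  net$out$b <- ps[["out.b"]]
  net
}

grads_flat <- function(grads, net) {
  ps <- list()
  for (i in seq_along(net$layers))
    for (nm in c("W", "b", "gamma", "beta"))
      ps[[paste0("l", i, ".", nm)]] <- grads$layers[[i]][[nm]]
  ps[["out.W"]] <- grads$out$W
  ps[["out.b"]] <- grads$out$b
  ps
}

## -- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

# Decoupled weight decay is applied to weight matrices only (names ending in
# ".W"), never to biases or layer-norm affine parameters.
adamw_update <- function(params, grads, state, lr, weight_decay = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    p <- params[[nm]] - lr * step
    if (weight_decay > 0 && grepl("\\.W$", nm))
      p <- p - lr * weight_decay * params[[nm]]
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

# cosine-annealing learning rate, single period, floor at 0
lr_cosine <- function(step, total, lr0) {
  lr0 * 0.5 * (1 + cos(pi * min(step, total) / total))
}

## -- losses ----------------------------------------------------------------

# numerically stable row-wise softmax cross-entropy; returns loss and
# gradient w.r.t. the logits (already divided by n)
softmax_ce <- function(logits, labels) {
  n <- nrow(logits); C <- ncol(logits)
  if (any(labels < 1L | labels > C))
    stop("class label outside logit range", call. = FALSE)
  mx <- logits[cbind(seq_len(n), max.col(logits, ties.method = "first"))]
  Z <- exp(logits - mx)
  s <- rowSums(Z)
  P <- Z / s
  idx <- cbind(seq_len(n), labels)
  loss <- mean(log(s) + mx - logits[idx])
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, grad = G / n, prob = P)
}

# row-wise L2 normalization and its backward pass
l2_normalize <- function(U) {
  nrm <- sqrt(rowSums(U^2))
  nrm <- pmax(nrm, 1e-12)
  list(Z = U / nrm, nrm = nrm)
}

l2_normalize_backward <- function(dZ, Z, nrm) {
  (dZ - rowSums(dZ * Z) * Z) / nrm
}
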