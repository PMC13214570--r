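# Shared fixtures: all synthetic, generated in code at test time.

# minimal cohort for mechanics tests (not powered for statistics)
tiny_cohort <- function(seed = 1L, ...) {
  generate_cohort(cohort_config(n_hc = 4L, n_pd = 2L,
                                n_voxels_per_subject = 150L,
                                n_features = 10L, seed = seed, ...))
}

# test-scale training profiles used by the pipeline-level tests: narrow
# nets and short schedules so the suite stays fast; the statistical
# structure of the task is unchanged
test_embed_config <- function(input_dim = 40L, seed = 1L, ...) {
  embedder_config(input_dim = input_dim, hidden = c(64L, 64L),
                  head_hidden = c(64L, 64L), steps = 200L,
                  batch_size = 160L, coord_bins = 8L, lr = 1e-3,
                  seed = seed, ...)
}

test_reg_config <- function(input_dim = 16L, seed = 1L, ...) {
  regressor_config(input_dim = input_dim, hidden = c(64L, 64L, 64L),
                   epochs = 30L, batch_size = 512L, lr = 1e-3,
                   seed = seed, ...)
}

# finite-difference gradient of a scalar function of a parameter list,
# checked at a few sampled coordinates per tensor
fd_check <- function(loss_fn, params, grads, n_per = 3L, eps = 1e-6,
                     seed = 42L) {
  worst <- 0
  set.seed(seed)
  for (nm in names(params)) {
    k <- min(n_per, length(params[[nm]]))
    for (i in sample(length(params[[nm]]), k)) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      an <- grads[[nm]][i]
      worst <- max(worst, abs(fd - an) / max(1e-8, abs(fd) + abs(an)))
    }
  }
  worst
}

# brute-force double-loop InfoNCE oracle (independent of the vectorized
# implementation)
nce_oracle <- function(Z, tau) {
  n2 <- nrow(Z); N <- n2 / 2; tot <- 0
  for (i in seq_len(n2)) {
    p <- if (i <= N) i + N else i - N
    num <- exp(sum(Z[i, ] * Z[p, ]) / tau)
    den <- 0
    for (k in seq_len(n2)) if (k != i) den <- den + exp(sum(Z[i, ] * Z[k, ]) / tau)
    tot <- tot - log(num / den)
  }
  tot / n2
}

random_unit_rows <- function(n, d, seed = 1L) {
  set.seed(seed)
  U <- matrix(rnorm(n * d), n, d)
  U / sqrt(rowSums(U^2))
}
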