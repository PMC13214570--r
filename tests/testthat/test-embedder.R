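test_that("InfoNCE matches the explicit double-loop oracle", {
  for (N in c(2, 4, 32)) {
    Z <- random_unit_rows(2 * N, 16, seed = N)
    expect_equal(info_nce(Z[1:N, ], Z[N + 1:N, ], 0.07),
                 nce_oracle(Z, 0.07), tolerance = 1e-6)
  }
  # all-identical embeddings: every term equal, loss = log(2N - 1)
  one <- matrix(1, 2, 3)
  expect_equal(info_nce(one, one, 0.07), log(3), tolerance = 1e-12)
  # aligned positives, orthogonal negatives, tau -> 0: loss -> 0
  Z <- rbind(diag(4), diag(4))
  expect_lt(info_nce(Z[1:4, ], Z[5:8, ], 1e-3), 1e-8)
  expect_error(info_nce(matrix(0, 2, 3), matrix(0, 3, 3)), "shapes")
})

test_that("InfoNCE gradient agrees with finite differences", {
  U <- matrix(rnorm(8 * 5), 8, 5)
  loss_u <- function(U) {
    Z <- datmap:::l2_normalize(U)$Z
    datmap:::info_nce_grad(Z, 0.07)$loss
  }
  nr <- datmap:::l2_normalize(U)
  an <- datmap:::l2_normalize_backward(
    datmap:::info_nce_grad(nr$Z, 0.07)$dZ, nr$Z, nr$nrm)
  eps <- 1e-6; worst <- 0
  set.seed(15)
  for (i in sample(length(U), 12)) {
    U1 <- U; U1[i] <- U1[i] + eps
    U2 <- U; U2[i] <- U2[i] - eps
    fd <- (loss_u(U1) - loss_u(U2)) / (2 * eps)
    worst <- max(worst, abs(fd - an[i]) / max(1e-8, abs(fd) + abs(an[i])))
  }
  expect_lt(worst, 1e-5)
})

test_that("quantile binning is balanced, clamped, and validated", {
  coords <- cbind(runif(32), runif(32), runif(32))
  set.seed(16)
  coords[] <- runif(96)
  bins <- coord_bin_edges(coords, n_bins = 16)
  expect_length(bins$edges[[1]], 17L)       # 17 edges for 16 bins
  lab <- discretize_coords(coords, bins)
  expect_true(all(table(lab[, 1]) == 2))    # 32 uniform values -> 2 per bin
  # out-of-range coordinates clamp to the end bins
  out <- discretize_coords(rbind(c(-99, -99, -99), c(99, 99, 99)), bins)
  expect_equal(unname(out[1, ]), c(1L, 1L, 1L))
  expect_equal(unname(out[2, ]), c(16L, 16L, 16L))
  # occupancy within +/-1 of equal share vs a sort-based oracle
  set.seed(17)
  big <- cbind(rnorm(500), rexp(500), runif(500))
  b2 <- coord_bin_edges(big, n_bins = 8)
  l2 <- discretize_coords(big, b2)
  for (a in 1:3) {
    occ <- tabulate(l2[, a], 8)
    expect_lte(max(abs(occ - 500 / 8)), 1)
  }
  bad <- b2; bad$edges[[2]] <- rev(bad$edges[[2]])
  expect_error(discretize_coords(big, bad), "monotone")
})

test_that("adversarial losses sit at chance for uninformative heads", {
  nb <- 16L
  ch <- datmap:::mlp_init(4, c(8), 3 * nb, dropout = 0, seed = 18)
  sh <- datmap:::mlp_init(4, c(8), 20L, dropout = 0, seed = 19)
  # zero the output layers: logits become constant -> uniform softmax
  ch$out$W[] <- 0; ch$out$b[] <- 0
  sh$out$W[] <- 0; sh$out$b[] <- 0
  Z <- random_unit_rows(10, 4, seed = 20)
  lab <- cbind(sample(nb, 10, TRUE), sample(nb, 10, TRUE), sample(nb, 10, TRUE))
  al <- adversarial_losses(Z, lab, sample(20, 10, TRUE), ch, sh, n_bins = nb)
  expect_equal(al$coordinate, log(16), tolerance = 1e-12)
  expect_equal(al$subject, log(20), tolerance = 1e-12)
})

test_that("gradient reversal flips and scales the encoder gradient exactly", {
  set.seed(21)
  enc <- datmap:::mlp_init(10, c(12, 12), 6, dropout = 0, seed = 22)
  head <- datmap:::mlp_init(6, c(16), 4, "ln_relu", dropout = 0, seed = 23)
  X <- matrix(rnorm(80), 8, 10)
  lab <- sample(4, 8, TRUE)
  for (lam in c(1, 1.7)) {
    gr <- datmap:::grl_encoder_gradient(enc, head, X, lab, w = 20,
                                        lambda = lam, reversed = TRUE)
    gu <- datmap:::grl_encoder_gradient(enc, head, X, lab, w = 20,
                                        lambda = lam, reversed = FALSE)
    for (nm in names(gr$grads))
      expect_lt(max(abs(gr$grads[[nm]] + lam * gu$grads[[nm]])), 1e-6)
  }
})

test_that("embeddings are unit-norm, deterministic, and dimension-checked", {
  co <- tiny_cohort(seed = 9)
  cop <- preprocess_cohort(co)
  v <- cop$voxels
  tr <- v$group == "HC" & v$subject_id %in% c("HC01", "HC02")
  ec <- embedder_config(input_dim = ncol(cop$features), hidden = c(24, 24),
                        head_hidden = c(24L), steps = 40, batch_size = 64,
                        coord_bins = 4, lr = 1e-3, seed = 5)
  # constant augmentation strength so the contrastive objective is
  # stationary and its loss comparable across steps
  em <- train_embedder(cop$features[tr, ], as.matrix(v[tr, c("x", "y", "z")]),
                       v$subject_id[tr], ec,
                       aug_config = augmentation_config(ramp_shape = "constant"))
  Z <- predict(em, cop$features[1:50, ])
  expect_lt(max(abs(sqrt(rowSums(Z^2)) - 1)), 1e-6)
  expect_identical(Z, predict(em, cop$features[1:50, ]))
  expect_equal(ncol(Z), 16L)
  expect_error(predict(em, cop$features[1:5, 1:3]), "expects")
  # training bookkeeping
  expect_equal(nrow(em$traces), 40L)
  expect_length(em$bins$edges[[1]], 5L)
  # contrastive objective made progress
  expect_lt(em$traces[40, "contrastive"], em$traces[1, "contrastive"])
  # single training subject is rejected
  one <- v$subject_id == "HC01"
  expect_error(train_embedder(cop$features[one, ],
                              as.matrix(v[one, c("x", "y", "z")]),
                              v$subject_id[one], ec), "2 training subjects")
})

test_that("checkpoints round-trip and embeddings stay informative", {
  co <- tiny_cohort(seed = 21)
  cop <- preprocess_cohort(co)
  v <- cop$voxels
  tr <- v$group == "HC"
  ec <- embedder_config(input_dim = ncol(cop$features), hidden = c(24, 24),
                        head_hidden = c(24L), steps = 50, batch_size = 64,
                        coord_bins = 4, lr = 1e-3, seed = 6)
  em <- train_embedder(cop$features[tr, ], as.matrix(v[tr, c("x", "y", "z")]),
                       v$subject_id[tr], ec)
  path <- withr::local_tempfile(fileext = ".rds")
  save_embedder(em, path)
  em2 <- load_embedder(path)
  expect_identical(predict(em2, cop$features[1:20, ]),
                   predict(em, cop$features[1:20, ]))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_loss_traces(em, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 50L)
  expect_named(tab, c("step", "contrastive", "coordinate", "subject"))
  # embeddings are not collapsed: a linear probe recovers the ground-truth
  # latent tissue factor with positive R^2
  Z <- predict(em, cop$features[tr, ])
  target <- co$truth$latent_maps[v$voxel[tr], 1]
  fit <- lm(target ~ Z)
  expect_gt(summary(fit)$r.squared, 0.05)
})
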