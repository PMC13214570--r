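test_that("degree-4 basis has the stars-and-bars term count", {
  expect_equal(nrow(polynomial_basis(4)$exponents), choose(4 + 3, 3))  # 35
  expect_equal(nrow(polynomial_basis(3)$exponents), choose(3 + 3, 3))  # 20
  g <- datmap:::build_grid(200L)
  Phi <- datmap:::design_matrix(g$coords, polynomial_basis(4))
  expect_equal(ncol(Phi), 35L)
  expect_equal(qr(Phi)$rank, 35L)
})

test_that("polynomial inputs detrend to zero and residuals are orthogonal", {
  g <- datmap:::build_grid(300L)
  U <- datmap:::normalize_bbox(g$coords)
  # features inside the basis span (degrees 0 and 3)
  X <- cbind(2 + U[, 1]^2 * U[, 2],
             1 - 0.5 * U[, 3]^3 + U[, 1] * U[, 2] * U[, 3])
  res <- polynomial_detrend(X, g$coords)
  expect_lt(max(abs(res)) / max(abs(X)), 1e-8)

  set.seed(1)
  Xr <- matrix(rnorm(nrow(U) * 3), ncol = 3)
  resr <- polynomial_detrend(Xr, g$coords)
  Phi <- datmap:::design_matrix(g$coords, polynomial_basis(4))
  expect_lt(max(abs(crossprod(Phi, resr))) / max(abs(Xr)), 1e-7)
})

test_that("detrending matches the normal-equations oracle and is idempotent", {
  g <- datmap:::build_grid(250L)
  set.seed(2)
  X <- matrix(rnorm(nrow(g$coords) * 4), ncol = 4)
  res <- polynomial_detrend(X, g$coords)
  # independent oracle: explicit normal equations
  Phi <- datmap:::design_matrix(g$coords, polynomial_basis(4))
  beta <- solve(crossprod(Phi), crossprod(Phi, X))
  oracle <- X - Phi %*% beta
  expect_lt(max(abs(res - oracle)) / max(abs(X)), 1e-8)
  # idempotence
  res2 <- polynomial_detrend(res, g$coords)
  expect_lt(max(abs(res2 - res)) / max(abs(X)), 1e-8)
})

test_that("degenerate detrending inputs raise informative errors", {
  g <- datmap:::build_grid(200L)
  X <- matrix(rnorm(20), 20, 1)
  expect_error(polynomial_detrend(X, g$coords[1:20, ]), "fewer voxels")
  set.seed(5)
  flat <- cbind(runif(100, -30, 30), runif(100, -20, 20), 0)
  # planar slab: z has a single distinct value
  expect_error(polynomial_detrend(matrix(rnorm(100), 100, 1), flat),
               "axis z")
})

test_that("z-scoring gives exact per-subject moments and handles degeneracy", {
  set.seed(3)
  X <- matrix(rnorm(400), 100, 4)
  ids <- rep(c("a", "b"), each = 50)
  zs <- zscore_per_subject(X, ids)
  for (id in c("a", "b")) {
    sub <- zs$features[ids == id, ]
    expect_lt(max(abs(colMeans(sub))), 1e-10)
    expect_lt(max(abs(colMeans(sub^2) - 1)), 1e-10)
  }
  # scale invariance: same signal at different per-subject scales
  X2 <- rbind(X[1:50, ], 7 * X[1:50, ])
  zs2 <- zscore_per_subject(X2, ids)
  expect_equal(zs2$features[1:50, ], zs2$features[51:100, ], tolerance = 1e-12)
  # rank order within subject and channel preserved
  expect_identical(order(zs$features[ids == "a", 1]), order(X[ids == "a", 1]))
  # constant channel is flagged and dropped
  Xc <- cbind(X, 5)
  expect_message(zs3 <- zscore_per_subject(Xc, ids), "degenerate")
  expect_equal(zs3$dropped, 5L)
  expect_equal(ncol(zs3$features), 4L)
})

test_that("atlas standardization uses population sd and inverts exactly", {
  st <- standardize_atlas(c(1, 2, 3))
  expect_equal(st$values, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(st$sd, sqrt(2 / 3))
  set.seed(4)
  a <- runif(50)
  st2 <- standardize_atlas(a)
  expect_lt(max(abs(invert_atlas(st2$values, st2) - a)), 1e-12)
  expect_error(standardize_atlas(rep(2, 10)), "constant")
})

test_that("exclusions remove what they are told and nothing else", {
  co <- tiny_cohort(seed = 5)
  expect_identical(apply_exclusions(co), co)   # exclude nothing: unchanged
  expect_error(apply_exclusions(co, subjects = "HC99"), "HC99")
  expect_error(apply_exclusions(co, channels = 99L), "channel")
  expect_message(ex <- apply_exclusions(co, subjects = "HC02", channels = c(1L, 3L)),
                 "3 subjects|5 subjects")
  expect_false("HC02" %in% ex$voxels$subject_id)
  expect_equal(ncol(ex$features), ncol(co$features) - 2L)
  # excluded subject absent from all downstream folds
  plans <- make_folds(ex$voxels)
  ids <- unlist(lapply(plans, function(p) c(p$train_hc, p$heldout_hc)))
  expect_false("HC02" %in% ids)
})

test_that("detrending removes the planted polynomial bias field", {
  co <- generate_cohort(cohort_config(n_hc = 3, n_pd = 1,
                                      n_voxels_per_subject = 1000,
                                      n_features = 8, bias_amplitude = 3,
                                      seed = 6))
  cop <- preprocess_cohort(co)
  v <- cop$voxels
  cors <- numeric(0)
  for (s in seq_along(co$truth$bias_coefficients)) {
    id <- co$truth$subject_ids[s]
    field <- attr(co$truth$bias_coefficients[[s]], "field")
    sub <- cop$features[v$subject_id == id, , drop = FALSE]
    cors <- c(cors, abs(cor(sub, field)))
  }
  expect_lt(mean(cors), 0.05)
  expect_lt(max(cors), 0.12)   # individual channels only chance-level
})
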