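test_that("generation is deterministic and structurally consistent", {
  co1 <- tiny_cohort(seed = 7)
  co2 <- tiny_cohort(seed = 7)
  expect_identical(co1$features, co2$features)
  expect_identical(co1$voxels, co2$voxels)

  # shared grid: every subject has identical coordinates and atlas values
  v <- co1$voxels
  ref <- v[v$subject_id == "HC01", c("voxel", "x", "y", "z", "atlas", "roi")]
  for (id in unique(v$subject_id)) {
    cur <- v[v$subject_id == id, c("voxel", "x", "y", "z", "atlas", "roi")]
    rownames(cur) <- rownames(ref) <- NULL
    expect_identical(cur, ref)
  }
  expect_false(anyNA(co1$features))
  expect_setequal(c("putamen", "caudate", "control"), levels(co1$roi))
  # different seed changes the data
  expect_false(identical(co1$features, tiny_cohort(seed = 8)$features))
})

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(n_hc = 2), "n_hc")
  expect_error(cohort_config(disease_attenuation = 1.5), "disease_attenuation")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(gain_amplitude = -0.1), "gain_amplitude")
  expect_error(cohort_config(n_rois = 2), "n_rois")
  expect_error(cohort_config(age_range_hc = c(70, 22)), "age_range_hc")
})

test_that("synthetic atlas is striatally elevated, smooth-deterministic", {
  g <- datmap:::build_grid(800L)
  a1 <- sample_atlas(g$coords, seed = 3)
  a2 <- sample_atlas(g$coords, seed = 3)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0))
  roi <- datmap:::assign_rois(g$U)
  striatal <- roi %in% c("putamen", "caudate")
  expect_gt(mean(a1[striatal]), mean(a1[!striatal]))
  expect_gt(cor(a1, as.numeric(striatal)), 0.5)
  expect_error(sample_atlas(matrix(numeric(), 0, 3)), "empty")
})

test_that("attenuation scales the atlas-linked component as specified", {
  # estimator: per group, regression slope of the loading-projection on the
  # standardized atlas over putamen voxels; the HC - PD slope difference
  # estimates the planted attenuation (tissue contributions cancel)
  slope_diff <- function(seed, atten) {
    co <- generate_cohort(cohort_config(n_hc = 4, n_pd = 4,
                                        n_voxels_per_subject = 300,
                                        n_features = 20,
                                        disease_attenuation = atten,
                                        seed = seed))
    L <- co$truth$loading
    proj <- as.numeric(co$features %*% L) / sum(L^2)
    v <- co$voxels
    put <- v$roi == "putamen"
    y <- co$truth$atlas_std[v$voxel[put]]
    sl <- function(grp) {
      sel <- put & v$group == grp
      yy <- co$truth$atlas_std[v$voxel[sel]]
      stats::cov(proj[sel], yy) / stats::var(yy)
    }
    sl("HC") - sl("PD")
  }
  diffs <- vapply(1:30, slope_diff, numeric(1), atten = 0.5)
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 0.5), 3 * mc_se)

  # no planted effect -> slope difference centered on zero
  diffs0 <- vapply(1:30, slope_diff, numeric(1), atten = 0)
  expect_lt(abs(mean(diffs0)), 3 * sd(diffs0) / sqrt(length(diffs0)))
})

test_that("groups are exchangeable when no effect is planted", {
  # subject-level permutation test on the putamen loading-projection mean;
  # under exchangeability rejections at alpha = 0.01 should be rare
  pvals <- vapply(1:20, function(seed) {
    co <- generate_cohort(cohort_config(n_hc = 6, n_pd = 4,
                                        n_voxels_per_subject = 150,
                                        n_features = 12,
                                        disease_attenuation = 0,
                                        seed = seed))
    L <- co$truth$loading
    proj <- as.numeric(co$features %*% L)
    v <- co$voxels
    put <- v$roi == "putamen"
    pm <- tapply(proj[put], v$subject_id[put], mean)
    grp <- tapply(as.character(v$group), v$subject_id, `[`, 1)[names(pm)]
    obs <- abs(mean(pm[grp == "HC"]) - mean(pm[grp == "PD"]))
    set.seed(seed)
    perm <- replicate(199, {
      gp <- sample(grp)
      abs(mean(pm[gp == "HC"]) - mean(pm[gp == "PD"]))
    })
    (1 + sum(perm >= obs)) / 200
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 19L)
})

test_that("planted effect is restricted to the putamen-like ROI", {
  # nuisance amplitudes kept low so group-mean fluctuations of the bias and
  # gain draws (5 subjects per group) do not mask the ROI-restriction claim
  co <- generate_cohort(cohort_config(n_hc = 5, n_pd = 5,
                                      n_voxels_per_subject = 400,
                                      n_features = 20,
                                      disease_attenuation = 1,
                                      bias_amplitude = 0.3,
                                      subject_bias_amplitude = 0.1,
                                      gain_amplitude = 0.1,
                                      seed = 2))
  L <- co$truth$loading
  proj <- as.numeric(co$features %*% L) / sum(L^2)
  v <- co$voxels
  for (rn in c("caudate", "control")) {
    sel <- v$roi == rn
    d <- mean(proj[sel & v$group == "HC"]) - mean(proj[sel & v$group == "PD"])
    expect_lt(abs(d), 0.15)   # no group difference off-target
  }
  selp <- v$roi == "putamen"
  dput <- mean(proj[selp & v$group == "HC"]) - mean(proj[selp & v$group == "PD"])
  expect_gt(abs(dput), 0.3)   # full attenuation clearly visible on-target
})

test_that("TSV round trip preserves the voxel table", {
  co <- tiny_cohort(seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(co, path)
  back <- read_cohort_tsv(path)
  expect_equal(back$features, co$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$voxels$subject_id, co$voxels$subject_id)
  expect_equal(back$voxels$atlas, co$voxels$atlas, tolerance = 1e-12)
})
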