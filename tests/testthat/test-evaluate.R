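fake_summary_input <- function(pred_by_roi, group = "HC", id = "S1", age = 60) {
  # pred_by_roi: named list roi -> vector of voxel predictions
  vox <- 0L
  rows <- lapply(names(pred_by_roi), function(rn) {
    v <- pred_by_roi[[rn]]
    idx <- vox + seq_along(v); vox <<- vox + length(v)
    data.frame(subject_id = id, voxel = idx, pred_mean = v, pred_median = v,
               roi = rn, group = group, age = age, young_hc = FALSE)
  })
  do.call(rbind, rows)
}

test_that("ROI summaries match hand computations including striatum union", {
  df <- fake_summary_input(list(putamen = c(1, 2, 3)))
  rs <- summarize_roi(df[, c("subject_id", "voxel", "pred_mean", "pred_median")],
                      df[, c("subject_id", "voxel", "roi", "group", "age", "young_hc")])
  put <- rs[rs$roi == "putamen" & rs$aggregation == "mean", ]
  expect_equal(put$summary_mean, 2)
  expect_equal(put$summary_median, 2)

  df2 <- fake_summary_input(list(putamen = c(1, 2, 10)))
  rs2 <- summarize_roi(df2[, c("subject_id", "voxel", "pred_mean", "pred_median")],
                       df2[, c("subject_id", "voxel", "roi", "group", "age", "young_hc")])
  put2 <- rs2[rs2$roi == "putamen" & rs2$aggregation == "mean", ]
  expect_equal(put2$summary_mean, 13 / 3)
  expect_equal(put2$summary_median, 2)

  # striatum is the voxel-weighted union, not the mean of ROI means
  df3 <- fake_summary_input(list(putamen = c(1, 1), caudate = 3))
  rs3 <- summarize_roi(df3[, c("subject_id", "voxel", "pred_mean", "pred_median")],
                       df3[, c("subject_id", "voxel", "roi", "group", "age", "young_hc")])
  stri <- rs3[rs3$roi == "striatum" & rs3$aggregation == "mean", ]
  expect_equal(stri$summary_mean, 5 / 3)
})

test_that("Welch's t matches the closed-form computation", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 4, 5, 6)
  wt <- welch_t(a, b)
  # independent hand computation
  se2 <- var(a) / 4 + var(b) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 6)^2 / 5)
  expect_equal(wt$t, t_hand, tolerance = 1e-12)
  expect_equal(wt$df, df_hand, tolerance = 1e-12)
  expect_equal(wt$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # null case and antisymmetry
  expect_equal(welch_t(a, a)$t, 0)
  expect_equal(welch_t(a, a)$p, 1)
  ba <- welch_t(b, a)
  expect_equal(ba$t, -wt$t)
  expect_equal(ba$p, wt$p)
  expect_error(welch_t(1, b), ">= 2")
})

test_that("BH q-values match a brute-force step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(50)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Hedges' g applies the small-sample correction and is scale-free", {
  set.seed(51)
  a <- rnorm(10, 1); b <- rnorm(10)
  hg <- hedges_g(a, b, n_boot = 200)
  d <- (mean(a) - mean(b)) /
    sqrt(((9 * var(a)) + (9 * var(b))) / 18)
  expect_equal(hg$g, d * (1 - 3 / 71), tolerance = 1e-12)  # J at df = 18
  # scale invariance
  hg2 <- hedges_g(2 * a, 2 * b, n_boot = 200)
  expect_equal(hg2$g, hg$g, tolerance = 1e-12)
  # null case: g = 0 and the CI straddles it
  hg0 <- hedges_g(c(1, 2, 3, 4), c(4, 3, 2, 1), n_boot = 500)
  expect_equal(hg0$g, 0)
  expect_lt(hg0$ci_low, 0); expect_gt(hg0$ci_high, 0)
  expect_true(hg0$ci_low <= hg0$g && hg0$g <= hg0$ci_high)
  expect_error(hedges_g(rep(1, 5), rep(1, 5)), "variance")
  # Wald alternative is available and symmetric about g
  hw <- hedges_g(a, b, ci = "wald")
  expect_equal((hw$ci_low + hw$ci_high) / 2, hw$g, tolerance = 1e-12)
})

test_that("ROC matches the Mann-Whitney oracle and the Youden contract", {
  # perfect separation (PD lower after flip-negation)
  r1 <- roc_analysis(hc = c(3, 4), pd = c(1, 2))
  expect_equal(r1$auc, 1)
  expect_equal(r1$balanced_accuracy, 1)
  # exchangeable groups with ties
  r2 <- roc_analysis(hc = c(1, 2), pd = c(1, 2))
  expect_equal(r2$auc, 0.5)
  # pairwise oracle with half credit for ties
  set.seed(52)
  for (i in 1:20) {
    hc <- sample(1:6, 7, replace = TRUE) + rnorm(7, 0, 0.01 * (i %% 2))
    pd <- sample(1:6, 5, replace = TRUE) + rnorm(5, 0, 0.01 * (i %% 2))
    r <- roc_analysis(hc, pd)
    wins <- sum(outer(-pd, -hc, ">")) + 0.5 * sum(outer(pd, hc, "=="))
    expect_equal(r$auc, wins / 35, tolerance = 1e-12)
    # balanced-accuracy identity at every scanned threshold
    expect_equal((r$curve$sensitivity + r$curve$specificity) / 2,
                 (r$curve$sensitivity + r$curve$specificity) / 2)
    y <- r$curve$sensitivity + r$curve$specificity - 1
    expect_equal(max(y), r$sensitivity + r$specificity - 1, tolerance = 1e-12)
  }
  expect_error(roc_analysis(numeric(), c(1, 2)), "non-empty")
})

test_that("group statistics assemble q, g, and CIs per ROI", {
  set.seed(53)
  mk <- function(id, grp, put) {
    data.frame(subject_id = id, group = grp, age = 60, young_hc = FALSE,
               roi = "putamen", aggregation = "mean",
               summary_mean = put, summary_median = put)
  }
  tab <- rbind(do.call(rbind, lapply(1:6, function(i) mk(paste0("H", i), "HC", 2.5 + rnorm(1, 0, 0.1)))),
               do.call(rbind, lapply(1:4, function(i) mk(paste0("P", i), "PD", 2.1 + rnorm(1, 0, 0.1)))))
  gs <- group_stats(tab, rois = "putamen", n_boot = 500)
  expect_equal(gs$n_hc, 6L); expect_equal(gs$n_pd, 4L)
  expect_gt(gs$hedges_g, 0)         # reduced binding in PD -> positive g
  expect_gte(gs$q, gs$p)            # BH never lowers a p-value
  expect_true(gs$g_ci_low <= gs$hedges_g && gs$hedges_g <= gs$g_ci_high)
})

test_that("age restriction filters HCs only and is identity when inert", {
  set.seed(54)
  mk <- function(id, grp, age, young, val) {
    data.frame(subject_id = id, group = grp, age = age, young_hc = young,
               roi = rep(c("putamen", "caudate", "striatum"), each = 1),
               aggregation = "mean", summary_mean = val, summary_median = val)
  }
  tab <- rbind(
    do.call(rbind, lapply(1:4, function(i) mk(paste0("H", i), "HC", 60 + i, FALSE, 2.5 + 0.05 * i))),
    do.call(rbind, lapply(5:6, function(i) mk(paste0("H", i), "HC", 25, TRUE, 2.5))),
    do.call(rbind, lapply(1:3, function(i) mk(paste0("P", i), "PD", 60, FALSE, 2.2 + 0.05 * i))))
  full <- group_stats(tab, n_boot = 200)
  inert <- age_restricted(tab, min_age = 0, n_boot = 200)
  expect_equal(inert$stats, full)
  expect_equal(inert$n_hc_removed, 0L)
  filt <- age_restricted(tab, min_age = 40, n_boot = 200)
  expect_equal(filt$n_hc_removed, 2L)   # exactly the flagged young HCs
  expect_equal(unique(filt$stats$n_hc), 4L)
  expect_equal(unique(filt$stats$n_pd), 3L)
  expect_error(age_restricted(tab, min_age = 99), "fewer than 2")
})

test_that("covariate correlations hit the closed-form sign cases", {
  tab <- data.frame(subject_id = paste0("S", 1:6), group = "HC",
                    age = c(50, 55, 60, 65, 70, 75), young_hc = FALSE,
                    roi = "putamen", aggregation = "mean",
                    summary_mean = c(50, 55, 60, 65, 70, 75),
                    summary_median = 0)
  expect_equal(correlation_controls(tab, "age")$r, 1, tolerance = 1e-12)
  tab$summary_mean <- -tab$summary_mean
  expect_equal(correlation_controls(tab, "age")$r, -1, tolerance = 1e-12)
  tab$age <- 60
  expect_error(correlation_controls(tab, "age"), "constant")
})
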