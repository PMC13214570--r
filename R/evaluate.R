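# ROI-level group statistics on the cross-validated predictions: per-subject
# ROI summaries, two-sided Welch's t-tests with Benjamini-Hochberg FDR
# across ROIs, Hedges' g with a seeded percentile-bootstrap 95% CI, ROC
# analysis with the Youden operating point (scores negated so that lower
# predicted binding reads as more PD-like), and the age-restricted control.

#' Summarize predictions per subject and ROI
#'
#' For each subject and each of putamen, caudate and striatum (the
#' voxel-level union of putamen and caudate), reports the mean and median of
#' the voxel predictions.  Subjects with an empty ROI are flagged and
#' excluded.
#'
#' @param aggregated a `dat_aggregated` (or `dat_loho`) object, or a data
#'   frame with `subject_id`, `voxel`, `pred_mean`, `pred_median`.
#' @param voxels cohort voxel table supplying `roi`, `group`, `age`,
#'   `young_hc` per (subject, voxel).
#' @param rois optional named list mapping summary ROI names to base ROI
#'   labels; defaults to every base label present plus `striatum`, the
#'   voxel-level union of putamen and caudate.
#' @return data frame of class `roi_summary`: one row per subject x ROI x
#'   aggregation method with `summary_mean` and `summary_median`.
#' @export
summarize_roi <- function(aggregated, voxels, rois = NULL) {
  if (inherits(aggregated, "dat_loho")) aggregated <- aggregated$aggregated
  pred <- if (is.data.frame(aggregated)) aggregated else aggregated$predictions
  meta <- voxels[, c("subject_id", "voxel", "roi", "group", "age", "young_hc")]
  m <- merge(pred, meta, by = c("subject_id", "voxel"), sort = FALSE)
  if (is.null(rois)) {
    base <- as.character(unique(m$roi))
    rois <- c(stats::setNames(as.list(base), base),
              list(striatum = c("putamen", "caudate")))
  }
  out <- list()
  for (agg in c("mean", "median")) {
    col <- paste0("pred_", agg)
    for (rn in names(rois)) {
      sel <- m[m$roi %in% rois[[rn]], , drop = FALSE]
      for (id in unique(m$subject_id)) {
        v <- sel[[col]][sel$subject_id == id]
        if (!length(v)) {
          warning(sprintf("subject %s has no voxels in ROI %s; excluded", id, rn))
          next
        }
        i <- match(id, m$subject_id)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = id, group = as.character(m$group[i]), age = m$age[i],
          young_hc = m$young_hc[i], roi = rn, aggregation = agg,
          summary_mean = mean(v), summary_median = stats::median(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("roi_summary", class(res))
  res
}

#' Two-sided Welch's t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @return list with `t`, `p` (two-sided), and `df`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs >= 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    stop("zero variance in both samples with unequal means", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return q-values in the input order (`q >= p` elementwise, clipped at 1).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Hedges' g with percentile-bootstrap confidence interval
#'
#' Cohen's d with pooled standard deviation (df = n1 + n2 - 2) times the
#' small-sample correction `J = 1 - 3 / (4 df - 1)`.  The 95% CI is a
#' seeded percentile bootstrap by default; `ci = "wald"` gives the analytic
#' normal-approximation interval.
#'
#' @param a,b numeric samples (positive g means `mean(a) > mean(b)`).
#' @param ci `"bootstrap"` or `"wald"`.
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return list with `g`, `ci_low`, `ci_high`.
#' @export
hedges_g <- function(a, b, ci = c("bootstrap", "wald"), n_boot = 10000L,
                     conf = 0.95, seed = 1L) {
  ci <- match.arg(ci)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each sample needs >= 2 observations", call. = FALSE)
  g_of <- function(x, y) {
    df <- length(x) + length(y) - 2L
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) / df
    if (sp2 <= 0) return(NA_real_)
    (mean(x) - mean(y)) / sqrt(sp2) * (1 - 3 / (4 * df - 1))
  }
  g <- g_of(a, b)
  if (is.na(g)) stop("zero pooled variance", call. = FALSE)
  alpha <- (1 - conf) / 2
  if (ci == "bootstrap") {
    bs <- with_seed(derive_seed(seed, 77L), {
      vapply(seq_len(n_boot), function(i)
        g_of(sample(a, n1, replace = TRUE), sample(b, n2, replace = TRUE)),
        numeric(1))
    })
    bs <- bs[is.finite(bs)]
    qs <- stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE)
  } else {
    df <- n1 + n2 - 2L
    se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * df))
    z <- stats::qnorm(1 - alpha)
    qs <- c(g - z * se, g + z * se)
  }
  list(g = g, ci_low = qs[1], ci_high = qs[2])
}

#' ROC analysis with the Youden operating point
#'
#' HCs are the negative class and PD the positive class.  Because disease
#' lowers predicted binding, the score is the negated ROI summary ("flipped"
#' ROC), so AUC >= 0.5 when PD predictions are lower.  Thresholds are
#' scanned at midpoints between consecutive sorted scores (plus open
#' endpoints); the Youden index (sensitivity + specificity - 1) picks the
#' operating point, ties broken toward higher specificity, and the threshold
#' is reported back on the binding-potential scale.  The AUC from the sweep
#' equals the Mann-Whitney statistic with half credit for ties.
#'
#' @param hc,pd numeric ROI summaries for the two groups.
#' @param flip negate summaries so that lower binding scores as PD-like
#'   (default `TRUE`).
#' @return list of class `roc_result` with `auc`, `threshold` (binding-
#'   potential scale), `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `flipped`, and the full sweep `curve`.
#' @export
roc_analysis <- function(hc, pd, flip = TRUE) {
  if (!length(hc) || !length(pd)) stop("both groups must be non-empty", call. = FALSE)
  s_hc <- if (flip) -hc else hc
  s_pd <- if (flip) -pd else pd
  all_s <- sort(unique(c(s_hc, s_pd)))
  mids <- if (length(all_s) > 1L)
    (all_s[-1] + all_s[-length(all_s)]) / 2 else numeric()
  thr <- c(min(all_s) - 1, mids, max(all_s) + 1)
  sens <- vapply(thr, function(t) mean(s_pd >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s_hc < t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[which.max(spec[best])]
  structure(list(auc = auc,
                 threshold = if (flip) -thr[best] else thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 balanced_accuracy = (sens[best] + spec[best]) / 2,
                 flipped = flip,
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC %.3f | Youden threshold %.3f (binding potential)\n",
              if (x$flipped) "flipped: low binding = PD-like" else "unflipped",
              x$auc, x$threshold))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, balanced accuracy %.3f\n",
              x$sensitivity, x$specificity, x$balanced_accuracy))
  invisible(x)
}

#' ROI-level group statistics table
#'
#' For each ROI: Welch's t, two-sided p, BH q across the tested ROIs,
#' Hedges' g (HC minus PD, so positive g means reduced binding in PD) with
#' 95% CI, and group sizes.
#'
#' @param roi_summary a [summarize_roi()] table.
#' @param aggregation `"mean"` or `"median"` (fold-aggregation method).
#' @param rois ROIs to test (the BH family; default putamen, caudate,
#'   striatum).
#' @param summary_col which per-subject ROI summary to test (default
#'   `"summary_mean"`, the ROI mean).
#' @param n_boot,seed bootstrap settings for the g CI.
#' @return data frame of class `group_stats` with one row per ROI.
#' @export
group_stats <- function(roi_summary, aggregation = "mean",
                        rois = c("putamen", "caudate", "striatum"),
                        summary_col = "summary_mean",
                        n_boot = 10000L, seed = 1L) {
  tab <- roi_summary[roi_summary$aggregation == aggregation, , drop = FALSE]
  rows <- lapply(rois, function(rn) {
    sel <- tab[tab$roi == rn, , drop = FALSE]
    a <- sel[[summary_col]][sel$group == "HC"]
    b <- sel[[summary_col]][sel$group == "PD"]
    wt <- welch_t(a, b)
    hg <- hedges_g(a, b, n_boot = n_boot, seed = derive_seed(seed, match(rn, rois)))
    data.frame(roi = rn, t = wt$t, p = wt$p, df = wt$df,
               hedges_g = hg$g, g_ci_low = hg$ci_low, g_ci_high = hg$ci_high,
               n_hc = length(a), n_pd = length(b), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res <- res[, c("roi", "t", "p", "q", "df", "hedges_g", "g_ci_low",
                 "g_ci_high", "n_hc", "n_pd")]
  class(res) <- c("group_stats", class(res))
  res
}

#' Age-restricted control analysis
#'
#' Re-runs the group statistics and putamen ROC after excluding HC subjects
#' below the age cutoff (no retraining; predictions are reused).
#'
#' @param roi_summary a [summarize_roi()] table.
#' @param min_age retain HCs with `age >= min_age` (PD always retained).
#' @param aggregation,rois,summary_col,n_boot,seed as in [group_stats()].
#' @return list with `stats` (group stats on the filtered cohort), `roc`
#'   (putamen ROC), `n_hc_removed`.
#' @export
age_restricted <- function(roi_summary, min_age, aggregation = "mean",
                           rois = c("putamen", "caudate", "striatum"),
                           summary_col = "summary_mean",
                           n_boot = 10000L, seed = 1L) {
  keep <- roi_summary$group != "HC" | roi_summary$age >= min_age
  filt <- roi_summary[keep, , drop = FALSE]
  n_hc <- length(unique(filt$subject_id[filt$group == "HC"]))
  if (n_hc < 2L) stop("age filter leaves fewer than 2 HCs", call. = FALSE)
  st <- group_stats(filt, aggregation = aggregation, rois = rois,
                    summary_col = summary_col, n_boot = n_boot, seed = seed)
  sel <- filt[filt$roi == "putamen" & filt$aggregation == aggregation, , drop = FALSE]
  roc <- roc_analysis(sel[[summary_col]][sel$group == "HC"],
                      sel[[summary_col]][sel$group == "PD"])
  list(stats = st, roc = roc,
       n_hc_removed = length(unique(roi_summary$subject_id[roi_summary$group == "HC"])) - n_hc)
}

#' Pearson correlation between ROI summaries and a per-subject covariate
#'
#' @param roi_summary a [summarize_roi()] table.
#' @param covariate column name in the summary table (e.g. `"age"`) or a
#'   named numeric vector keyed by subject id.
#' @param roi,aggregation,summary_col which summaries to correlate.
#' @return list with `r` and `p` (two-sided).
#' @export
correlation_controls <- function(roi_summary, covariate = "age",
                                 roi = "putamen", aggregation = "mean",
                                 summary_col = "summary_mean") {
  sel <- roi_summary[roi_summary$roi == roi &
                       roi_summary$aggregation == aggregation, , drop = FALSE]
  x <- if (is.character(covariate) && length(covariate) == 1L)
    sel[[covariate]] else unname(covariate[sel$subject_id])
  y <- sel[[summary_col]]
  if (length(unique(x)) < 2L) stop("constant covariate", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @export
print.group_stats <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) signif(v, 3))
  print(y, row.names = FALSE)
  invisible(x)
}
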