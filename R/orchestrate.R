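# Leave-one-HC-out cross-validation.  Each fold trains the embedder and the
# regressor on all healthy controls but one; the held-out HC and every PD
# subject are pure test subjects in every fold, so patients never influence
# training.  Fold manifests record the training subjects for leakage audits.

#' Build the leave-one-HC-out fold plan
#'
#' One fold per healthy control, ordered by subject id; PD subjects are test
#' subjects in every fold.
#'
#' @param voxels cohort voxel table (needs `subject_id` and `group`).
#' @param seed global seed from which per-fold seeds are derived.
#' @return list of fold plans, each with `fold`, `train_hc`, `heldout_hc`,
#'   `pd_ids`, and `seed`.
#' @export
make_folds <- function(voxels, seed = 1L) {
  sub <- unique(voxels[, c("subject_id", "group")])
  hc <- sort(sub$subject_id[sub$group == "HC"])
  pd <- sort(sub$subject_id[sub$group == "PD"])
  if (length(hc) < 3L) stop("need >= 3 healthy controls for leave-one-out", call. = FALSE)
  lapply(seq_along(hc), function(k) {
    list(fold = k,
         train_hc = setdiff(hc, hc[k]),
         heldout_hc = hc[k],
         pd_ids = pd,
         seed = derive_seed(seed, k))
  })
}

#' Run one leave-one-HC-out fold
#'
#' Trains the embedder on the fold's training HCs only, embeds the whole
#' cohort with the frozen encoder, trains the regressor on the training
#' HCs' embeddings only, and predicts the held-out HC plus all PD subjects
#' on the binding-potential scale.
#'
#' @param plan one element of [make_folds()].
#' @param cohort a preprocessed `dat_cohort` (see [preprocess_cohort()]).
#' @param embed_config,reg_config,aug_config stage configurations; the fold
#'   seed is injected into the stage seeds.
#' @param ablation `"none"` (main pipeline), `"raw"` (regressor on the
#'   preprocessed features directly, no embedder), or `"no_adversarial"`
#'   (embedder trained with `w_coord = w_subject = 0`).
#' @return list of class `dat_fold` with `predictions` (data frame: subject,
#'   voxel, prediction), the fold `manifest`, and the fitted states.
#' @export
run_fold <- function(plan, cohort, embed_config, reg_config,
                     aug_config = augmentation_config(),
                     ablation = c("none", "raw", "no_adversarial")) {
  ablation <- match.arg(ablation)
  vox <- cohort$voxels
  if (is.null(cohort$prep))
    stop("cohort must be preprocessed (see preprocess_cohort)", call. = FALSE)
  train_rows <- vox$subject_id %in% plan$train_hc
  test_ids <- c(plan$heldout_hc, plan$pd_ids)
  test_rows <- vox$subject_id %in% test_ids

  atlas_std_all <- (vox$atlas - cohort$prep$atlas_stats$mean) /
    cohort$prep$atlas_stats$sd

  embedder <- NULL
  if (ablation == "raw") {
    Z_train <- cohort$features[train_rows, , drop = FALSE]
    Z_test <- cohort$features[test_rows, , drop = FALSE]
    reg_dim <- ncol(cohort$features)
  } else {
    ec <- embed_config
    ec$seed <- derive_seed(plan$seed, 41L)
    if (ablation == "no_adversarial") {
      ec$w_coord <- 0
      ec$w_subject <- 0
    }
    embedder <- train_embedder(cohort$features[train_rows, , drop = FALSE],
                               as.matrix(vox[train_rows, c("x", "y", "z")]),
                               vox$subject_id[train_rows],
                               config = ec, aug_config = aug_config)
    Z_train <- predict(embedder, cohort$features[train_rows, , drop = FALSE])
    Z_test <- predict(embedder, cohort$features[test_rows, , drop = FALSE])
    reg_dim <- ec$embed_dim
  }

  rc <- reg_config
  rc$seed <- derive_seed(plan$seed, 42L)
  rc$input_dim <- reg_dim
  regressor <- train_regressor(Z_train, atlas_std_all[train_rows], rc)
  pred_bp <- predict_dat(regressor, Z_test, cohort$prep$atlas_stats)

  structure(list(
    fold = plan$fold,
    predictions = data.frame(subject_id = vox$subject_id[test_rows],
                             voxel = vox$voxel[test_rows],
                             prediction = pred_bp,
                             stringsAsFactors = FALSE),
    manifest = list(fold = plan$fold, training_subjects = plan$train_hc,
                    heldout_hc = plan$heldout_hc, pd_ids = plan$pd_ids,
                    ablation = ablation, seed = plan$seed),
    embedder = embedder, regressor = regressor),
    class = "dat_fold")
}

#' Aggregate fold predictions across the cross-validation
#'
#' Held-out-HC predictions come from each HC's own fold and are never
#' aggregated; PD predictions are aggregated per voxel across folds by both
#' the mean and the median.
#'
#' @param folds list of `dat_fold` results (all folds present).
#' @param voxels the cohort voxel table (for group labels).
#' @return list of class `dat_aggregated` with a long data frame
#'   `predictions` (columns `subject_id`, `voxel`, `pred_mean`,
#'   `pred_median`) and the fold manifests.
#' @export
aggregate_predictions <- function(folds, voxels) {
  if (!length(folds)) stop("no folds to aggregate", call. = FALSE)
  n_folds <- length(folds)
  hc_fold <- vapply(folds, function(f) f$manifest$heldout_hc, character(1))
  if (anyDuplicated(hc_fold) || n_folds != length(unique(hc_fold)))
    stop("missing or duplicated fold", call. = FALSE)

  hc_parts <- lapply(folds, function(f) {
    p <- f$predictions
    p[p$subject_id == f$manifest$heldout_hc, , drop = FALSE]
  })
  hc_df <- do.call(rbind, hc_parts)
  hc_df$pred_mean <- hc_df$prediction
  hc_df$pred_median <- hc_df$prediction
  hc_df$prediction <- NULL

  pd_stack <- lapply(folds, function(f) {
    p <- f$predictions
    p <- p[p$subject_id %in% f$manifest$pd_ids, , drop = FALSE]
    p[order(p$subject_id, p$voxel), , drop = FALSE]
  })
  key <- paste(pd_stack[[1]]$subject_id, pd_stack[[1]]$voxel)
  M <- vapply(pd_stack, function(p) {
    if (!identical(paste(p$subject_id, p$voxel), key))
      stop("fold PD prediction sets disagree", call. = FALSE)
    p$prediction
  }, numeric(length(key)))
  if (length(key) == 1L) M <- matrix(M, nrow = 1L)
  pd_df <- data.frame(subject_id = pd_stack[[1]]$subject_id,
                      voxel = pd_stack[[1]]$voxel,
                      pred_mean = rowMeans(M),
                      pred_median = apply(M, 1L, stats::median),
                      stringsAsFactors = FALSE)

  structure(list(predictions = rbind(hc_df, pd_df),
                 manifests = lapply(folds, `[[`, "manifest"),
                 n_folds = n_folds),
            class = "dat_aggregated")
}

#' Run the full leave-one-HC-out pipeline on a preprocessed cohort
#'
#' Preprocessing (subject-wise, leakage-free) is applied once if needed;
#' folds then run sequentially, each with derived seeds, and predictions are
#' aggregated.
#'
#' @param cohort a `dat_cohort` (preprocessed or raw).
#' @param embed_config,reg_config,aug_config stage configurations.
#' @param seed global pipeline seed (per-fold seeds are derived from it).
#' @param ablation `"none"`, `"raw"`, or `"no_adversarial"` (see
#'   [run_fold()]).
#' @param keep_folds retain per-fold states (default `FALSE` keeps only
#'   predictions and manifests).
#' @return list of class `dat_loho` with the aggregated predictions, fold
#'   manifests, and the preprocessed cohort reference.
#' @export
run_loho <- function(cohort, embed_config, reg_config,
                     aug_config = augmentation_config(), seed = 1L,
                     ablation = c("none", "raw", "no_adversarial"),
                     keep_folds = FALSE) {
  ablation <- match.arg(ablation)
  if (is.null(cohort$prep)) cohort <- preprocess_cohort(cohort)
  plans <- make_folds(cohort$voxels, seed = seed)
  folds <- lapply(plans, run_fold, cohort = cohort,
                  embed_config = embed_config, reg_config = reg_config,
                  aug_config = aug_config, ablation = ablation)
  agg <- aggregate_predictions(folds, cohort$voxels)
  out <- structure(list(aggregated = agg, manifests = agg$manifests,
                        ablation = ablation, seed = seed, cohort = cohort),
                   class = "dat_loho")
  if (keep_folds) out$folds <- folds
  out
}

#' Run an ablation variant of the pipeline
#'
#' `"raw"` trains the regressor directly on the preprocessed multispectral
#' features (no embedder); `"no_adversarial"` trains the embedder with
#' `w_coord = w_subject = 0`.  Everything else (folds, seeds, aggregation)
#' is identical to the main pipeline.
#'
#' @inheritParams run_loho
#' @param mode `"raw"` or `"no_adversarial"`.
#' @export
run_ablation <- function(cohort, mode = c("raw", "no_adversarial"),
                         embed_config, reg_config,
                         aug_config = augmentation_config(), seed = 1L) {
  mode <- match.arg(mode)
  run_loho(cohort, embed_config, reg_config, aug_config, seed = seed,
           ablation = mode)
}

#' @export
print.dat_loho <- function(x, ...) {
  cat(sprintf("leave-one-HC-out run: %d folds, ablation = %s\n",
              x$aggregated$n_folds, x$ablation))
  cat(sprintf("  %d test predictions (%d subjects)\n",
              nrow(x$aggregated$predictions),
              length(unique(x$aggregated$predictions$subject_id))))
  invisible(x)
}
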