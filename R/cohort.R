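# Synthetic multispectral cohort generator.  Emulates the statistical
# structure the pipeline assumes: a latent tissue signal linked to a
# normative DaT atlas, subject-specific smooth spatial bias fields exactly
# representable in the degree-4 monomial basis (so detrending must remove
# them), a sharp residual subject bias that survives detrending and
# z-scoring (what the subject adversary suppresses), per-channel gains,
# measurement noise, and a group-specific attenuation of the atlas-linked
# component restricted to a putamen-like ROI of PD subjects.  Optional
# knobs add per-subject channel-mixing jitter and monotone intensity
# warps for robustness studies.

# physical half-extent of the slab grid, mm-like units per normalized axis
GRID_SCALE <- c(30, 20, 8)

PUTAMEN_CENTER <- c(-0.45, -0.15, 0)
PUTAMEN_RADII  <- c(0.50, 0.55, 0.85)
CAUDATE_CENTER <- c(0.45, 0.20, 0)
CAUDATE_RADII  <- c(0.45, 0.50, 0.80)

#' Configuration for a synthetic multispectral cohort
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's validation: 8 healthy controls (HC) and 4 Parkinson's disease
#' (PD) subjects with 40 feature channels; the full-scale cohort analogue
#' would use 21 HC / 10 PD with 349 channels.
#'
#' @param n_hc,n_pd number of healthy-control and patient subjects
#'   (`n_hc >= 3` so leave-one-out retains at least two training HCs).
#' @param n_voxels_per_subject voxels per subject on the shared slab grid.
#' @param n_features number of feature channels.
#' @param n_rois number of ROI labels (>= 3: putamen-like, caudate-like,
#'   control; extra labels split the control region).
#' @param disease_attenuation fraction in `[0, 1]` by which the atlas-linked
#'   signal component is attenuated in affected-ROI voxels of PD subjects.
#' @param bias_poly_degree polynomial degree of the planted spatial bias
#'   fields (default 4, matching the detrending model).
#' @param bias_amplitude,gain_amplitude,noise_sd nonnegative scalars setting
#'   the bias-field standard deviation, the per-channel gain spread, and the
#'   measurement-noise standard deviation.
#' @param subject_bias_amplitude standard deviation of a subject-specific
#'   *residual* intensity bias: sharp (non-polynomial) spatial fields times
#'   per-channel profiles.  Unlike the `bias_amplitude` component it
#'   survives degree-4 detrending and per-subject z-scoring, emulating the
#'   residual B0/B1 inhomogeneity that reveals subject identity and that
#'   the adversarial heads are designed to suppress.
#' @param mixing_jitter relative per-subject perturbation of the
#'   tissue-to-channel mixing matrix (scanner/session differences in
#'   channel geometry).  Off-diagonal mixing changes survive per-channel
#'   z-scoring; invariance to them is what the subject adversary buys.
#' @param subject_warp_sd log-scale standard deviation of per-subject,
#'   per-channel monotone gamma-like intensity warps (non-linear readout
#'   differences between sessions).  Warps survive z-scoring (which is
#'   affine); the view-augmentation set explicitly emulates them, so the
#'   contrastive encoder is trained to be invariant while a regressor on
#'   raw features must overfit the training subjects' warps.
#' @param n_latent number of latent tissue factors (first factor is the
#'   standardized atlas itself, so tissue is correlated with the target).
#' @param atlas_loading_frac fraction of channels carrying atlas-linked
#'   signal (sparse loading).
#' @param age_range_hc,age_range_pd per-group `(min, max)` age in years.
#' @param young_age_cutoff HC subjects below this age are flagged as the
#'   "young HC" subgroup used by the age-restricted control analysis.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 8L, n_pd = 4L,
                          n_voxels_per_subject = 1500L,
                          n_features = 40L,
                          n_rois = 3L,
                          disease_attenuation = 0.3,
                          bias_poly_degree = 4L,
                          bias_amplitude = 1.0,
                          gain_amplitude = 0.2,
                          noise_sd = 0.25,
                          subject_bias_amplitude = 0.3,
                          mixing_jitter = 0,
                          subject_warp_sd = 0,
                          n_latent = 5L,
                          atlas_loading_frac = 0.25,
                          age_range_hc = c(22, 70),
                          age_range_pd = c(48, 73),
                          young_age_cutoff = 40,
                          seed = 1L) {
  cfg <- list(n_hc = as.integer(n_hc), n_pd = as.integer(n_pd),
              n_voxels_per_subject = as.integer(n_voxels_per_subject),
              n_features = as.integer(n_features), n_rois = as.integer(n_rois),
              disease_attenuation = disease_attenuation,
              bias_poly_degree = as.integer(bias_poly_degree),
              bias_amplitude = bias_amplitude,
              gain_amplitude = gain_amplitude, noise_sd = noise_sd,
              subject_bias_amplitude = subject_bias_amplitude,
              mixing_jitter = mixing_jitter,
              subject_warp_sd = subject_warp_sd,
              n_latent = as.integer(n_latent),
              atlas_loading_frac = atlas_loading_frac,
              age_range_hc = age_range_hc, age_range_pd = age_range_pd,
              young_age_cutoff = young_age_cutoff, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_hc < 3L) stop_config("n_hc", "must be >= 3 (leave-one-out needs >= 2 training HCs)")
  if (cfg$n_pd < 1L) stop_config("n_pd", "must be >= 1")
  if (cfg$n_voxels_per_subject < 64L) stop_config("n_voxels_per_subject", "must be >= 64")
  if (cfg$n_features < 2L) stop_config("n_features", "must be >= 2")
  if (cfg$n_rois < 3L) stop_config("n_rois", "must be >= 3")
  if (cfg$disease_attenuation < 0 || cfg$disease_attenuation > 1)
    stop_config("disease_attenuation", "must be in [0, 1]")
  for (f in c("bias_amplitude", "gain_amplitude", "noise_sd",
              "subject_bias_amplitude", "mixing_jitter", "subject_warp_sd"))
    if (cfg[[f]] < 0) stop_config(f, "must be >= 0")
  if (cfg$n_latent < 1L) stop_config("n_latent", "must be >= 1")
  if (cfg$atlas_loading_frac <= 0 || cfg$atlas_loading_frac > 1)
    stop_config("atlas_loading_frac", "must be in (0, 1]")
  for (f in c("age_range_hc", "age_range_pd")) {
    r <- cfg[[f]]
    if (length(r) != 2L || r[1] > r[2]) stop_config(f, "must be (min, max) with min <= max")
  }
  invisible(cfg)
}

# fixed slab lattice shared by all subjects; normalized coords in [-1, 1]^3
# with fewer samples along z (slab geometry)
build_grid <- function(n_voxels) {
  # at least degree + 1 = 5 distinct z planes so degree-4 detrending is
  # full rank on the slab
  nz <- max(5L, round((n_voxels / 20)^(1 / 3)))
  nxy <- ceiling(sqrt(n_voxels / nz))
  gx <- seq(-1, 1, length.out = nxy)
  gz <- seq(-1, 1, length.out = nz)
  # z varies fastest so truncating to exactly n_voxels trims the slow y
  # axis and always retains all nz >= 5 z planes (full rank for degree-4
  # fits along every axis)
  eg <- expand.grid(z = gz, x = gx, y = gx)
  U <- cbind(x = eg$x, y = eg$y, z = eg$z)
  U <- U[seq_len(min(n_voxels, nrow(U))), , drop = FALSE]
  dimnames(U) <- list(NULL, c("x", "y", "z"))
  list(U = U,
       coords = sweep(U, 2L, GRID_SCALE, "*"),
       dims = c(nxy, nxy, nz))
}

ellipse_q <- function(U, center, radii) {
  q <- 0
  for (a in 1:3) q <- q + ((U[, a] - center[a]) / radii[a])^2
  q
}

# ROI labels on the normalized grid: putamen-like and caudate-like
# ellipsoids, everything else control (optionally split into extra labels)
assign_rois <- function(U, n_rois = 3L) {
  put <- ellipse_q(U, PUTAMEN_CENTER, PUTAMEN_RADII) <= 1
  cau <- ellipse_q(U, CAUDATE_CENTER, CAUDATE_RADII) <= 1 & !put
  roi <- rep("control", nrow(U))
  roi[put] <- "putamen"
  roi[cau] <- "caudate"
  if (n_rois > 3L) {
    ctrl <- which(roi == "control")
    extra <- cut(U[ctrl, "z"], breaks = n_rois - 2L, labels = FALSE)
    roi[ctrl] <- ifelse(extra == 1L, "control", paste0("control", extra))
  }
  factor(roi)
}

# smooth seeded scalar field on the grid: mixture of broad Gaussian bumps
smooth_field <- function(U, n_bumps = 3L, width = 0.6, amp = 1) {
  f <- numeric(nrow(U))
  for (j in seq_len(n_bumps)) {
    c_j <- stats::runif(3, -1, 1)
    a_j <- stats::runif(1, 0, amp)
    d2 <- rowSums(sweep(U, 2L, c_j, "-")^2)
    f <- f + a_j * exp(-d2 / (2 * width^2))
  }
  f
}

#' Sample a synthetic normative DaT atlas on a coordinate grid
#'
#' Produces a smooth nonnegative binding-potential-like field, elevated
#' inside the striatum-like ROIs (putamen-like and caudate-like ellipsoids)
#' and low elsewhere, plus a seeded smooth background.
#'
#' @param coords voxel-by-3 coordinate matrix (any affine scaling of the
#'   slab; axes are renormalized to `[-1, 1]` by their bounding box).
#' @param seed integer seed for the smooth background component.
#' @return numeric vector of atlas values, one per row of `coords`.
#' @export
sample_atlas <- function(coords, seed = 1L) {
  if (is.null(dim(coords)) || nrow(coords) == 0L)
    stop("empty coordinate grid", call. = FALSE)
  U <- normalize_bbox(coords)
  with_seed(derive_seed(seed, 101L), {
    bg <- smooth_field(U, n_bumps = 3L, width = 0.7, amp = 0.3)
    # cubed quadratic form gives the steep binding falloff at the striatal
    # boundary seen in DaT atlases (and keeps the field outside the span of
    # low-order polynomials in the coordinates)
    0.3 + 2.2 * exp(-1.2 * ellipse_q(U, PUTAMEN_CENTER, PUTAMEN_RADII)^3) +
      1.8 * exp(-1.2 * ellipse_q(U, CAUDATE_CENTER, CAUDATE_RADII)^3) + bg
  })
}

# affine map of each axis to [-1, 1] over its bounding box
normalize_bbox <- function(coords) {
  U <- coords
  for (a in seq_len(ncol(coords))) {
    r <- range(coords[, a])
    U[, a] <- if (r[2] > r[1]) 2 * (coords[, a] - r[1]) / (r[2] - r[1]) - 1 else 0
  }
  U
}

#' Generate a synthetic multispectral cohort
#'
#' Voxel features follow
#' `(1 + gain) * (tissue + atlas_linked) + bias_field + noise`, where the
#' atlas-linked component `atlas_std * loading` is attenuated by
#' `disease_attenuation` in putamen-like voxels of PD subjects, the bias
#' field is a subject-specific degree-4 polynomial in the voxel coordinates
#' (times a per-channel profile), and gains are subject- and channel-
#' specific.  Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `dat_cohort`: a list with `voxels` (long-format
#'   metadata data frame), `features` (row-aligned voxel-by-channel matrix),
#'   `truth` (generative ground truth for recovery tests), `grid`, and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  grid <- build_grid(cfg$n_voxels_per_subject)
  V <- nrow(grid$U)
  Fn <- cfg$n_features
  roi <- assign_rois(grid$U, cfg$n_rois)
  atlas <- sample_atlas(grid$coords, seed = cfg$seed)
  atlas_std <- (atlas - mean(atlas)) / sd_pop(atlas)

  with_seed(derive_seed(cfg$seed, 7L), {
    # latent tissue factors: factor 1 is correlated with the atlas target
    # (r ~ 0.5) but distinct from it — the disease-sensitive atlas-linked
    # signal lives in the sparse loading, not in the tissue background
    K <- cfg$n_latent
    Tm <- matrix(0, V, K)
    f1 <- smooth_field(grid$U, n_bumps = 4L, width = 0.45, amp = 1)
    f1 <- (f1 - mean(f1)) / max(sd_pop(f1), 1e-12)
    Tm[, 1] <- 0.5 * atlas_std + sqrt(1 - 0.25) * f1
    if (K > 1) for (k in 2:K) {
      f <- smooth_field(grid$U, n_bumps = 4L, width = 0.45, amp = 1)
      Tm[, k] <- (f - mean(f)) / max(sd_pop(f), 1e-12)
    }
    mixing <- matrix(stats::rnorm(K * Fn, 0, 1 / sqrt(K)), K, Fn)

    # sparse atlas-linked loading
    n_active <- max(1L, round(cfg$atlas_loading_frac * Fn))
    active <- sort(sample.int(Fn, n_active))
    loading <- numeric(Fn)
    loading[active] <- stats::rnorm(n_active, 0, 1)

    # polynomial basis for the planted bias fields
    basis <- polynomial_basis(cfg$bias_poly_degree)
    Phi <- design_matrix(grid$coords, basis)

    n_sub <- cfg$n_hc + cfg$n_pd
    ids <- c(sprintf("HC%02d", seq_len(cfg$n_hc)),
             sprintf("PD%02d", seq_len(cfg$n_pd)))
    group <- rep(c("HC", "PD"), c(cfg$n_hc, cfg$n_pd))
    age <- c(stats::runif(cfg$n_hc, cfg$age_range_hc[1], cfg$age_range_hc[2]),
             stats::runif(cfg$n_pd, cfg$age_range_pd[1], cfg$age_range_pd[2]))

    affected <- roi == "putamen"

    gains <- matrix(stats::rnorm(n_sub * Fn, 0, cfg$gain_amplitude), n_sub, Fn)
    bias_coef <- vector("list", n_sub)
    bias_profile <- matrix(stats::rnorm(n_sub * Fn), n_sub, Fn)
    resid_profile <- matrix(stats::rnorm(n_sub * Fn), n_sub, Fn)
    resid_fields <- vector("list", n_sub)

    X <- matrix(0, n_sub * V, Fn)
    mixing_jit <- vector("list", n_sub)
    warps <- matrix(1, n_sub, Fn)
    for (s in seq_len(n_sub)) {
      atten <- rep(1, V)
      if (group[s] == "PD") atten[affected] <- 1 - cfg$disease_attenuation
      # per-subject channel geometry: jittered mixing matrix
      Ms <- mixing + cfg$mixing_jitter *
        matrix(stats::rnorm(K * Fn), K, Fn) / sqrt(K)
      mixing_jit[[s]] <- Ms
      signal <- Tm %*% Ms + (atlas_std * atten) %o% loading
      beta <- stats::rnorm(ncol(Phi))
      field <- drop(Phi %*% beta)
      fs <- sd_pop(field)
      if (fs > 0 && cfg$bias_amplitude > 0) {
        field <- field / fs * cfg$bias_amplitude
      } else field <- field * 0
      bias_coef[[s]] <- beta
      # residual subject bias: a sharp bump field (outside the degree-4
      # span) times a channel profile; survives detrending and z-scoring
      rf <- smooth_field(grid$U, n_bumps = 6L, width = 0.22, amp = 1)
      rsd <- sd_pop(rf)
      rf <- if (rsd > 0) (rf - mean(rf)) / rsd * cfg$subject_bias_amplitude else rf * 0
      resid <- rf %o% resid_profile[s, ]
      resid_fields[[s]] <- rf
      rows <- (s - 1L) * V + seq_len(V)
      Xs <- sweep(signal, 2L, 1 + gains[s, ], "*") + resid +
        matrix(stats::rnorm(V * Fn, 0, cfg$noise_sd), V, Fn)
      # per-subject monotone intensity warp (gamma-like, per channel),
      # applied before the polynomial bias so the planted smooth bias
      # remains exactly representable in the detrending basis
      if (cfg$subject_warp_sd > 0) {
        gam <- exp(stats::rnorm(Fn, 0, cfg$subject_warp_sd))
        warps[s, ] <- gam
        for (ch in seq_len(Fn)) {
          mn <- min(Xs[, ch]); mxx <- max(Xs[, ch])
          if (mxx > mn)
            Xs[, ch] <- ((Xs[, ch] - mn) / (mxx - mn))^gam[ch] * (mxx - mn) + mn
        }
      }
      X[rows, ] <- Xs + field %o% bias_profile[s, ]
      attr(bias_coef[[s]], "field") <- field
    }
    colnames(X) <- sprintf("f%03d", seq_len(Fn))

    voxels <- data.frame(
      subject_id = rep(ids, each = V),
      group = factor(rep(group, each = V), levels = c("HC", "PD")),
      age = rep(age, each = V),
      young_hc = rep(group == "HC" & age < cfg$young_age_cutoff, each = V),
      voxel = rep(seq_len(V), n_sub),
      x = rep(grid$coords[, 1], n_sub),
      y = rep(grid$coords[, 2], n_sub),
      z = rep(grid$coords[, 3], n_sub),
      roi = rep(roi, n_sub),
      atlas = rep(atlas, n_sub),
      stringsAsFactors = FALSE)

    truth <- list(latent_maps = Tm, mixing = mixing,
                  subject_mixing = mixing_jit, loading = loading,
                  active_channels = active, gains = gains,
                  bias_coefficients = bias_coef,
                  bias_channel_profiles = bias_profile,
                  residual_bias_fields = resid_fields,
                  residual_bias_profiles = resid_profile,
                  subject_warps = warps,
                  attenuation = cfg$disease_attenuation,
                  affected_roi = "putamen",
                  atlas = atlas, atlas_std = atlas_std,
                  subject_ids = ids, group = group, age = age)

    structure(list(voxels = voxels, features = X, truth = truth,
                   grid = grid, roi = roi, config = cfg),
              class = "dat_cohort")
  })
}

#' @export
print.dat_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic multispectral cohort: %d HC + %d PD, %d voxels/subject, %d channels\n",
              cfg$n_hc, cfg$n_pd, nrow(x$grid$U), cfg$n_features))
  cat(sprintf("  putaminal attenuation %.2f | bias sd %.2f | gain sd %.2f | noise sd %.2f\n",
              cfg$disease_attenuation, cfg$bias_amplitude,
              cfg$gain_amplitude, cfg$noise_sd))
  cat(sprintf("  ROI voxels: %s\n",
              paste(sprintf("%s=%d", levels(x$roi), table(x$roi)), collapse = ", ")))
  invisible(x)
}

#' Write a cohort voxel table as TSV
#'
#' One row per voxel with subject metadata, coordinates, ROI label, atlas
#' target, and the feature channels as `f001..fNNN` columns.
#'
#' @param cohort a `dat_cohort`.
#' @param path output file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  tab <- cbind(cohort$voxels, as.data.frame(cohort$features))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort voxel table written by [write_cohort_tsv()]
#'
#' @param path TSV file path.
#' @return a list with `voxels` and `features` in the same row order.
#' @export
read_cohort_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(tab))
  voxels <- tab[, -fcols, drop = FALSE]
  voxels$group <- factor(voxels$group, levels = c("HC", "PD"))
  voxels$roi <- factor(voxels$roi)
  list(voxels = voxels, features = as.matrix(tab[, fcols, drop = FALSE]))
}

#' Export per-subject feature volumes and the ROI label map as NIfTI
#'
#' Requires the `RNifti` package.  One 4-D volume per subject (x, y, z,
#' channel) plus `roi.nii.gz` (integer labels) and `atlas.nii.gz`.
#'
#' @param cohort a `dat_cohort`.
#' @param dir output directory (created if missing).
#' @export
write_cohort_nifti <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dims <- cohort$grid$dims
  V <- nrow(cohort$grid$U)
  to_vol <- function(v) {
    a <- array(NA_real_, dims)
    a[seq_len(V)] <- v
    a
  }
  RNifti::writeNifti(RNifti::asNifti(to_vol(as.integer(cohort$roi))),
                     file.path(dir, "roi.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(to_vol(cohort$truth$atlas)),
                     file.path(dir, "atlas.nii.gz"))
  ids <- unique(cohort$voxels$subject_id)
  for (id in ids) {
    rows <- cohort$voxels$subject_id == id
    Xs <- cohort$features[rows, , drop = FALSE]
    a <- array(NA_real_, c(dims, ncol(Xs)))
    for (ch in seq_len(ncol(Xs))) {
      sl <- array(NA_real_, dims); sl[seq_len(V)] <- Xs[, ch]
      a[, , , ch] <- sl
    }
    RNifti::writeNifti(RNifti::asNifti(a), file.path(dir, paste0(id, ".nii.gz")))
  }
  invisible(dir)
}
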