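# Spatial preprocessing: per-subject fourth-order polynomial detrending of
# every feature channel against voxel coordinates, per-subject/per-channel
# z-scoring of the residuals, and standardization of the atlas target.
# All operations are strictly subject-wise, so applying them before
# cross-validation leaks nothing across subjects.

#' Full tensor monomial basis of bounded total degree in three variables
#'
#' Terms are all monomials `x^a y^b z^c` with `a + b + c <= degree`;
#' for degree 4 this yields `choose(4 + 3, 3) = 35` terms.
#'
#' @param degree maximum total degree (default 4).
#' @return a list of class `polynomial_basis` with the ordered exponent
#'   triples.
#' @export
polynomial_basis <- function(degree = 4L) {
  degree <- as.integer(degree)
  if (degree < 0L) stop_config("degree", "must be >= 0")
  ex <- expand.grid(a = 0:degree, b = 0:degree, c = 0:degree)
  ex <- ex[rowSums(ex) <= degree, , drop = FALSE]
  ex <- ex[order(rowSums(ex), ex$a, ex$b, ex$c), ]
  structure(list(degree = degree, exponents = as.matrix(ex)),
            class = "polynomial_basis")
}

# design matrix of the basis on bbox-normalized coordinates
design_matrix <- function(coords, basis) {
  U <- normalize_bbox(as.matrix(coords))
  ex <- basis$exponents
  Phi <- matrix(1, nrow(U), nrow(ex))
  for (j in seq_len(nrow(ex))) {
    Phi[, j] <- U[, 1]^ex[j, 1] * U[, 2]^ex[j, 2] * U[, 3]^ex[j, 3]
  }
  colnames(Phi) <- apply(ex, 1L, function(e) sprintf("x%dy%dz%d", e[1], e[2], e[3]))
  Phi
}

#' Remove smooth spatial trends by polynomial least squares
#'
#' Fits, independently per channel, a polynomial in the (bbox-normalized)
#' voxel coordinates by QR least squares and returns the residuals.
#' Intended to be called once per subject.
#'
#' @param features voxel-by-channel numeric matrix for one subject.
#' @param coords voxel-by-3 coordinate matrix.
#' @param basis a [polynomial_basis()] (default degree 4).
#' @return residual matrix of the same shape; the fitted values are
#'   orthogonal to every basis column.
#' @export
polynomial_detrend <- function(features, coords, basis = polynomial_basis(4L)) {
  features <- as.matrix(features)
  coords <- as.matrix(coords)
  check_finite(features, "features")
  if (nrow(features) != nrow(coords))
    stop("features and coords disagree on voxel count", call. = FALSE)
  Phi <- design_matrix(coords, basis)
  if (nrow(Phi) < ncol(Phi))
    stop(sprintf("fewer voxels (%d) than basis terms (%d)", nrow(Phi), ncol(Phi)),
         call. = FALSE)
  qrx <- qr(Phi)
  if (qrx$rank < ncol(Phi)) {
    n_distinct <- apply(coords, 2L, function(v) length(unique(v)))
    bad <- which(n_distinct <= basis$degree)
    ax <- c("x", "y", "z")[if (length(bad)) bad[1] else 1L]
    stop(sprintf("rank-deficient polynomial design (axis %s has too few distinct coordinates)", ax),
         call. = FALSE)
  }
  res <- qr.resid(qrx, features)
  dimnames(res) <- dimnames(features)
  res
}

#' Per-subject, per-channel z-scoring
#'
#' Standardizes each channel to mean 0 and unit variance within each
#' subject, using the population (divide-by-n) standard deviation.
#' Channels whose within-subject standard deviation is (near) zero for any
#' subject are flagged degenerate and excluded from the output.
#'
#' @param residuals voxel-by-channel matrix (typically detrended).
#' @param subject_id optional vector of subject ids per row; if omitted the
#'   whole matrix is treated as one subject.
#' @param tol degeneracy tolerance on the standard deviation.
#' @return a list with `features` (standardized, degenerate channels
#'   dropped), `stats` (per-subject means/sds), and `dropped` (channel
#'   indices removed).
#' @export
zscore_per_subject <- function(residuals, subject_id = NULL, tol = 1e-10) {
  X <- as.matrix(residuals)
  check_finite(X, "residuals")
  if (is.null(subject_id)) subject_id <- rep("s1", nrow(X))
  subject_id <- as.character(subject_id)
  ids <- unique(subject_id)
  stats <- list()
  degen <- logical(ncol(X))
  Z <- X
  for (id in ids) {
    rows <- subject_id == id
    m <- colMeans(X[rows, , drop = FALSE])
    s <- col_sd_pop(X[rows, , drop = FALSE])
    degen <- degen | s < tol
    s_safe <- pmax(s, tol)
    Z[rows, ] <- sweep(sweep(X[rows, , drop = FALSE], 2L, m, "-"), 2L, s_safe, "/")
    stats[[id]] <- list(mean = m, sd = s)
  }
  dropped <- which(degen)
  if (length(dropped)) {
    message(sprintf("dropping %d degenerate (zero-variance) channel(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    Z <- Z[, -dropped, drop = FALSE]
  }
  list(features = Z, stats = stats, dropped = dropped)
}

#' Standardize the atlas target over an analysis mask
#'
#' @param atlas numeric atlas values.
#' @param mask optional logical mask (default: all voxels).
#' @return list with `values` (standardized over the mask, population sd),
#'   `mean`, `sd`; use [invert_atlas()] to return predictions to the
#'   original binding-potential scale.
#' @export
standardize_atlas <- function(atlas, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(atlas))
  v <- atlas[mask]
  if (length(unique(v)) < 2L) stop("constant atlas over the mask", call. = FALSE)
  m <- mean(v); s <- sd_pop(v)
  list(values = (atlas - m) / s, mean = m, sd = s)
}

#' Map standardized predictions back to the binding-potential scale
#'
#' @param values standardized values.
#' @param stats the list returned by [standardize_atlas()].
#' @export
invert_atlas <- function(values, stats) values * stats$sd + stats$mean

#' Remove subjects and/or feature channels from a cohort
#'
#' @param cohort a `dat_cohort` (or a list with `voxels` and `features`).
#' @param subjects character subject ids to drop.
#' @param channels integer indices or channel names to drop.
#' @return the filtered cohort; the remaining feature dimension is reported
#'   via `message()`.
#' @export
apply_exclusions <- function(cohort, subjects = character(), channels = integer()) {
  if (length(subjects)) {
    known <- unique(cohort$voxels$subject_id)
    unknown <- setdiff(subjects, known)
    if (length(unknown))
      stop(sprintf("unknown subject id(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    keep <- !(cohort$voxels$subject_id %in% subjects)
    cohort$voxels <- cohort$voxels[keep, , drop = FALSE]
    cohort$features <- cohort$features[keep, , drop = FALSE]
    rownames(cohort$voxels) <- NULL
  }
  if (length(channels)) {
    if (is.character(channels)) {
      idx <- match(channels, colnames(cohort$features))
      if (anyNA(idx))
        stop(sprintf("unknown channel(s): %s",
                     paste(channels[is.na(idx)], collapse = ", ")), call. = FALSE)
      channels <- idx
    }
    if (any(channels < 1L | channels > ncol(cohort$features)))
      stop("unknown channel index", call. = FALSE)
    cohort$features <- cohort$features[, -channels, drop = FALSE]
  }
  if (length(subjects) || length(channels))
    message(sprintf("after exclusions: %d subjects, %d feature channels",
                    length(unique(cohort$voxels$subject_id)), ncol(cohort$features)))
  cohort
}

#' Preprocess a cohort for embedding
#'
#' Per subject: polynomial detrending of every channel followed by
#' per-channel z-scoring; the atlas target is standardized over the grid.
#' Purely subject-wise, hence leakage-free when applied before
#' cross-validation.
#'
#' @param cohort a `dat_cohort`.
#' @param degree polynomial degree for detrending (default 4).
#' @return the cohort with `features` replaced by standardized residuals and
#'   a `prep` element holding the basis degree, per-subject statistics,
#'   dropped channels, and atlas standardization stats.
#' @export
preprocess_cohort <- function(cohort, degree = 4L) {
  basis <- polynomial_basis(degree)
  ids <- unique(cohort$voxels$subject_id)
  R <- cohort$features
  for (id in ids) {
    rows <- cohort$voxels$subject_id == id
    R[rows, ] <- polynomial_detrend(cohort$features[rows, , drop = FALSE],
                                    as.matrix(cohort$voxels[rows, c("x", "y", "z")]),
                                    basis)
  }
  zs <- zscore_per_subject(R, cohort$voxels$subject_id)
  atlas_by_voxel <- cohort$voxels$atlas[!duplicated(cohort$voxels$voxel)]
  atl <- standardize_atlas(atlas_by_voxel[order(unique(cohort$voxels$voxel))])
  cohort$features <- zs$features
  cohort$prep <- list(degree = degree, subject_stats = zs$stats,
                      dropped_channels = zs$dropped, atlas_stats = atl)
  cohort
}
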