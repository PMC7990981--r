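#' Design matrix for the voxelwise ageing model
#'
#' Columns `(intercept, age, sex)`; the default contrast `(0, -1, 0)` tests
#' metabolic decline with age (one-sided: large positive t = decline).
#'
#' @param meta Data.frame with columns `age` and `sex` (>= 5 subjects).
#' @param contrast Length-3 numeric contrast vector.
#' @return Object of class `design_matrix`: list with `X` (n x 3),
#'   `contrast`, `df` (n - 3).
#' @export
build_design_matrix <- function(meta, contrast = c(0, -1, 0)) {
  n <- nrow(meta)
  if (n < 5L) stop_("need at least 5 subjects, got %d", n)
  stopifnot(length(contrast) == 3L)
  X <- cbind(intercept = 1, age = meta$age, sex = as.numeric(meta$sex))
  if (qr(X)$rank < 3L) {
    stop_("design matrix is rank deficient (constant age or single-sex cohort)")
  }
  structure(list(X = X, contrast = as.numeric(contrast), df = n - 3L),
            class = "design_matrix")
}

# stack a list of 3-D volumes into an n x V matrix over the mask
stack_volumes <- function(volumes, mask) {
  idx <- which(mask)
  Y <- vapply(volumes, function(v) v[idx], numeric(length(idx)))
  t(Y)
}

#' Voxelwise ordinary least squares fit
#'
#' Fits `y(v) = X beta(v) + e(v)` independently at every in-mask voxel:
#' `beta_hat = (X'X)^{-1} X'y`, `sigma2_hat = RSS / (n - p)`.
#'
#' @param Y Numeric matrix, subjects x voxels (see [stack_volumes()]), or a
#'   list of 3-D volumes together with `mask`.
#' @param design A [build_design_matrix()] result.
#' @param mask Optional logical 3-D array; required when `Y` is a list of
#'   volumes.
#' @return List of class `voxel_fit`: `beta` (3 x V), `sigma2` (length V),
#'   `XtX_inv`, `df`, plus `mask`/`dim` when a mask was supplied.
#' @export
fit_voxelwise_ols <- function(Y, design, mask = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  dims <- NULL
  if (is.list(Y) && !is.matrix(Y)) {
    stopifnot(!is.null(mask), sum(mask) > 0L)
    dims <- dim(mask)
    Y <- stack_volumes(Y, mask)
  }
  X <- design$X
  stopifnot(nrow(Y) == nrow(X))
  if (!all(is.finite(Y))) {
    bad <- which(!apply(is.finite(Y), 2L, all))
    stop_("non-finite values at voxel(s): %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  XtY <- crossprod(X, Y)
  beta <- XtX_inv %*% XtY
  rss <- colSums(Y^2) - colSums(beta * XtY)
  rss <- pmax(rss, 0)  # guard tiny negatives from cancellation
  structure(list(beta = beta, sigma2 = rss / design$df,
                 XtX_inv = XtX_inv, df = design$df,
                 mask = mask, dim = dims),
            class = "voxel_fit")
}

#' Contrast t-statistics from a voxelwise fit
#'
#' `t(v) = c'beta(v) / sqrt(sigma2(v) * c'(X'X)^{-1} c)`. Degenerate voxels:
#' zero residual variance with a non-zero contrast value maps to a signed
#' infinity (a perfect effect); 0/0 maps to 0.
#'
#' @param fit A [fit_voxelwise_ols()] result.
#' @param contrast Length-3 contrast vector (default the design's own).
#' @return Numeric vector of t values (length V), or a 3-D t-map array when
#'   the fit carries a mask (out-of-mask voxels 0).
#' @export
contrast_tmap <- function(fit, contrast = c(0, -1, 0)) {
  stopifnot(inherits(fit, "voxel_fit"))
  if (length(contrast) != nrow(fit$beta)) {
    stop_("contrast length %d does not match %d regressors",
          length(contrast), nrow(fit$beta))
  }
  num <- as.numeric(crossprod(contrast, fit$beta))
  cvar <- as.numeric(t(contrast) %*% fit$XtX_inv %*% contrast)
  se <- sqrt(fit$sigma2 * cvar)
  t <- ifelse(se > 0, num / se, ifelse(num == 0, 0, sign(num) * Inf))
  if (!is.null(fit$mask)) {
    tmap <- array(0, dim = fit$dim)
    tmap[which(fit$mask)] <- t
    return(tmap)
  }
  t
}

# one-shot max t over the mask for a given age vector (permutation workhorse)
max_t_for_ages <- function(Y, ages, sexes, contrast, yty) {
  X <- cbind(1, ages, sexes)
  XtX_inv <- solve(crossprod(X))
  XtY <- crossprod(X, Y)
  beta <- XtX_inv %*% XtY
  rss <- pmax(yty - colSums(beta * XtY), 0)
  sigma2 <- rss / (nrow(X) - 3L)
  num <- as.numeric(crossprod(contrast, beta))
  se <- sqrt(sigma2 * as.numeric(t(contrast) %*% XtX_inv %*% contrast))
  t <- ifelse(se > 0, num / se, ifelse(num == 0, 0, sign(num) * Inf))
  max(t)
}

#' Permutation max-T family-wise error threshold
#'
#' Builds the null distribution of the maximum in-mask t statistic by
#' permuting the age values across subjects (sex stays attached to each
#' subject), and returns the `(1 - alpha)` empirical quantile, taken as the
#' `ceiling((1 - alpha) * (n_perm + 1))`-th order statistic of the `n_perm`
#' null maxima (clamped to at least the minimum). A t-map thresholded at
#' this value controls the family-wise error rate at `alpha`.
#'
#' @param Y Subjects x voxels matrix, or list of volumes with `mask`.
#' @param meta Data.frame with `age` and `sex`.
#' @param contrast Length-3 contrast (default decline, `(0, -1, 0)`).
#' @param n_perm Number of permutations, >= 100.
#' @param alpha Family-wise error level (default 0.05).
#' @param seed Integer seed; the threshold is deterministic given the seed.
#' @param mask Logical 3-D array when `Y` is a list of volumes.
#' @return The threshold t value, with the sorted null maxima attached as
#'   attribute `"null_max_t"`.
#' @export
permutation_fwe_threshold <- function(Y, meta, contrast = c(0, -1, 0),
                                      n_perm = 500L, alpha = 0.05,
                                      seed = 1L, mask = NULL) {
  if (n_perm < 100L) stop_("insufficient permutations (n_perm >= 100)")
  stopifnot(alpha > 0, alpha <= 1)
  if (is.list(Y) && !is.matrix(Y)) Y <- stack_volumes(Y, mask)
  n <- nrow(Y)
  yty <- colSums(Y^2)
  maxs <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      max_t_for_ages(Y, meta$age[sample.int(n)], as.numeric(meta$sex),
                     contrast, yty)
    }, numeric(1L))
  })
  srt <- sort(maxs)
  m <- max(1L, ceiling((1 - alpha) * (n_perm + 1L)))
  m <- min(m, n_perm)
  thr <- srt[m]
  attr(thr, "null_max_t") <- srt
  thr
}

#' Full voxelwise age-decline analysis for one normalization
#'
#' Fits the age + sex model at every in-mask voxel, thresholds the decline
#' t-map either at a permutation max-T FWE threshold or at a caller-supplied
#' fixed t value (used to carry one system's threshold over to another
#' cohort), labels supra-threshold clusters and reports their volumes.
#'
#' @param volumes List of subject volumes (or subjects x voxels matrix).
#' @param meta Data.frame with `age`, `sex`.
#' @param mask Logical 3-D array of analyzed voxels.
#' @param voxel_size_mm Numeric triple (mm).
#' @param alpha FWE level for the permutation threshold.
#' @param n_perm Permutations (>= 100).
#' @param seed Seed for the permutation null.
#' @param fixed_t Optional fixed threshold; skips the permutation step.
#' @param connectivity Cluster connectivity, 6, 18 or 26 (default 26).
#' @param contrast Length-3 contrast (default decline).
#' @return Object of class `glm_result`: `tmap` (3-D array), `beta`, `df`,
#'   `threshold_T`, `alpha`, `clusters` (data.frame), and
#'   `total_significant_mm3`.
#' @export
voxelwise_age_glm <- function(volumes, meta, mask, voxel_size_mm,
                              alpha = 0.05, n_perm = 500L, seed = 1L,
                              fixed_t = NULL, connectivity = 26L,
                              contrast = c(0, -1, 0)) {
  Y <- if (is.matrix(volumes)) volumes else stack_volumes(volumes, mask)
  design <- build_design_matrix(meta, contrast = contrast)
  fit <- fit_voxelwise_ols(Y, design)
  t_in_mask <- contrast_tmap(fit, contrast)
  tmap <- array(0, dim = dim(mask))
  tmap[which(mask)] <- t_in_mask
  threshold <- if (is.null(fixed_t)) {
    as.numeric(permutation_fwe_threshold(Y, meta, contrast, n_perm = n_perm,
                                         alpha = alpha, seed = seed))
  } else {
    as.numeric(fixed_t)
  }
  clusters <- label_clusters(tmap, threshold, voxel_size_mm,
                             connectivity = connectivity)
  structure(list(tmap = tmap, beta = fit$beta, df = fit$df,
                 threshold_T = threshold, alpha = alpha,
                 clusters = clusters,
                 total_significant_mm3 = sum(clusters$volume_mm3),
                 t_max = if (sum(mask)) max(t_in_mask) else -Inf),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("glm_result: threshold T = %.3f (df = %d), %d cluster(s), %s mm3 significant, t_max = %.2f\n",
              x$threshold_T, x$df, nrow(x$clusters),
              format(x$total_significant_mm3, big.mark = ","), x$t_max))
  invisible(x)
}
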