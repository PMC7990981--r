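make_meta <- function(n, seed = 1) {
  withr::with_seed(seed, {
    data.frame(subject_id = sprintf("S%02d", seq_len(n)),
               age = runif(n, 25, 85), sex = rep_len(c(0L, 1L), n))
  })
}

test_that("the design matrix has intercept/age/sex columns and guards rank", {
  meta <- make_meta(5)
  d <- build_design_matrix(meta)
  expect_identical(dim(d$X), c(5L, 3L))
  expect_true(all(d$X[, 1L] == 1))
  expect_identical(d$df, 2L)
  expect_equal(d$contrast, c(0, -1, 0))

  males <- meta
  males$sex <- 0L
  expect_error(build_design_matrix(males), "rank deficient")
  expect_error(build_design_matrix(meta[1:4, ]), "at least 5")
})

test_that("noiseless linear data recovers its coefficients exactly", {
  meta <- make_meta(10)
  y <- 2 - 0.03 * meta$age  # exact linear function of age, no noise
  Y <- cbind(y, y, y)
  fit <- fit_voxelwise_ols(Y, build_design_matrix(meta))
  expect_equal(unname(fit$beta[, 1L]), c(2, -0.03, 0), tolerance = 1e-10)
  expect_equal(unname(fit$sigma2), rep(0, 3L), tolerance = 1e-18)

  t <- contrast_tmap(fit)
  expect_identical(unname(t), rep(Inf, 3L))  # perfect decline
})

test_that("t statistics match an independent lm() oracle voxel by voxel", {
  meta <- make_meta(8, seed = 3)
  withr::with_seed(9, Y <- matrix(rnorm(8 * 20, 100, 5), 8, 20))
  fit <- fit_voxelwise_ols(Y, build_design_matrix(meta))
  t <- contrast_tmap(fit)
  for (v in seq_len(20L)) {
    expect_equal(t[v], lm_t_oracle(Y[, v], meta$age, meta$sex),
                 tolerance = 1e-10)
  }
  # flipping the contrast negates the map exactly
  expect_equal(contrast_tmap(fit, c(0, 1, 0)), -t, tolerance = 1e-14)
  expect_error(contrast_tmap(fit, c(0, -1)), "contrast length")
})

test_that("row permutations and age centering leave the t-map unchanged", {
  meta <- make_meta(12, seed = 5)
  withr::with_seed(10, Y <- matrix(rnorm(12 * 15, 50, 4), 12, 15))
  t0 <- contrast_tmap(fit_voxelwise_ols(Y, build_design_matrix(meta)))

  perm <- withr::with_seed(2, sample.int(12))
  t1 <- contrast_tmap(fit_voxelwise_ols(Y[perm, ],
                                        build_design_matrix(meta[perm, ])))
  expect_equal(t1, t0, tolerance = 1e-10)

  centered <- meta
  centered$age <- meta$age - mean(meta$age)
  t2 <- contrast_tmap(fit_voxelwise_ols(Y, build_design_matrix(centered)))
  expect_equal(t2, t0, tolerance = 1e-10)
})

test_that("non-finite voxel data is rejected with the voxel named", {
  meta <- make_meta(6)
  Y <- matrix(1, 6, 4) + rnorm(24)
  Y[3, 2] <- NA
  expect_error(fit_voxelwise_ols(Y, build_design_matrix(meta)), "voxel")
})

test_that("the permutation max-T threshold is seeded, bounded and alpha-monotone", {
  meta <- make_meta(14, seed = 6)
  withr::with_seed(11, Y <- matrix(rnorm(14 * 30), 14, 30))

  thr1 <- permutation_fwe_threshold(Y, meta, n_perm = 120L, seed = 42)
  thr2 <- permutation_fwe_threshold(Y, meta, n_perm = 120L, seed = 42)
  expect_identical(as.numeric(thr1), as.numeric(thr2))

  null_max <- attr(thr1, "null_max_t")
  expect_length(null_max, 120L)
  thr_all <- permutation_fwe_threshold(Y, meta, n_perm = 120L, alpha = 1,
                                       seed = 42)
  expect_equal(as.numeric(thr_all), min(null_max))  # alpha = 1: everything passes

  thr_strict <- permutation_fwe_threshold(Y, meta, n_perm = 120L,
                                          alpha = 0.01, seed = 42)
  expect_true(as.numeric(thr_strict) >= as.numeric(thr1))

  expect_error(permutation_fwe_threshold(Y, meta, n_perm = 50L, seed = 1),
               "insufficient permutations")
})

test_that("image-level and matrix-level normalization agree on piecewise-constant data", {
  atl <- toy_atlas_12()
  cfg <- cohort_config(16, 50, 12, 25, 80, 8, noise_sd = 0,
                       global_factor_sd = 0.2, smoothing_fwhm_mm = 0, seed = 9)
  model <- ageing_model_for_atlas(atl, seed = 9)
  gen <- generate_cohort(atl, cfg, model)
  mat <- uptake_matrix_from_volumes(gen$volumes, gen$meta, atl,
                                    whole_grey_matter = FALSE)

  suvr <- normalize_by_reference(mat, "Pons")
  design <- build_design_matrix(gen$meta)
  t_matrix <- contrast_tmap(fit_voxelwise_ols(suvr$values, design))

  denom <- mat$values[, "Pons"]
  vols_n <- lapply(seq_along(gen$volumes),
                   function(i) gen$volumes[[i]] / denom[i])
  mask <- atl$label_grid > 0L
  t_image <- contrast_tmap(fit_voxelwise_ols(vols_n, design, mask = mask))

  # every voxel of region k carries the t of matrix column k
  idx <- which(mask)
  lab <- atl$label_grid[idx]
  t_in_mask <- t_image[idx]
  for (k in seq_along(atl$region_names)) {
    tv <- unique(round(t_in_mask[lab == k], 6))
    expect_length(tv, 1L)
    if (is.finite(t_matrix[k])) {
      expect_equal(unique(t_in_mask[lab == k])[1L], t_matrix[k],
                   tolerance = 1e-10)
    }
  }
})
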