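test_that("regional means are plain voxel averages", {
  atl <- toy_atlas_12()
  const <- array(0, dim = dim(atl$label_grid))
  const[atl$label_grid > 0L] <- 3.0
  m <- extract_region_means(const, atl)
  expect_equal(unname(m), rep(3.0, 12L))

  # handmade two-voxel region
  labs <- array(0L, c(3, 3, 3))
  labs[1, 1, 1] <- 1L; labs[2, 1, 1] <- 1L; labs[3, 3, 3] <- 2L
  atl2 <- parcellation_atlas(labs, c("A", "B"), c(1, 1, 1))
  vol <- array(0, c(3, 3, 3))
  vol[1, 1, 1] <- 1; vol[2, 1, 1] <- 3; vol[3, 3, 3] <- 7
  expect_equal(unname(extract_region_means(vol, atl2)), c(2, 7))

  expect_error(extract_region_means(array(0, c(4, 4, 4)), atl2),
               "does not match")
})

test_that("extraction is affine-equivariant and whole grey matter is the weighted mean", {
  atl <- toy_atlas_12()
  withr::with_seed(11, {
    vol <- array(0, dim = dim(atl$label_grid))
    vol[atl$label_grid > 0L] <- runif(sum(atl$label_grid > 0L), 50, 150)
  })
  m <- extract_region_means(vol, atl)
  shifted <- vol
  shifted[atl$label_grid > 0L] <- 2.5 * vol[atl$label_grid > 0L] + 7
  expect_equal(unname(extract_region_means(shifted, atl)),
               unname(2.5 * m + 7), tolerance = 1e-12)

  full <- extract_region_means(vol, atl, whole_grey_matter = TRUE)
  counts <- tabulate(atl$label_grid[atl$label_grid > 0L], 12L)
  gm <- !is.element(atl$region_names, c("Pons", "Midbrain", "Medulla"))
  expect_equal(unname(full["Whole_grey_matter"]),
               sum(m[gm] * counts[gm]) / sum(counts[gm]), tolerance = 1e-10)
})

test_that("uptake matrix rows follow manifest order and carry metadata", {
  atl <- toy_atlas_12()
  cfg <- cohort_config(3, 50, 10, 20, 80, 1, noise_sd = 0.02,
                       smoothing_fwhm_mm = 0, seed = 2)
  model <- ageing_model_for_atlas(atl, seed = 2)
  gen <- generate_cohort(atl, cfg, model)
  out <- tempfile("cohort")
  manifest_path <- write_cohort(gen$meta, gen$volumes, out, atl$voxel_size_mm)

  mat <- build_uptake_matrix(manifest_path, atlas = atl)
  expect_identical(dim(mat$values), c(3L, 13L))  # 12 regions + whole grey matter
  expect_identical(mat$subject_ids, gen$meta$subject_id)
  expect_equal(mat$ages, gen$meta$age)

  # permuting manifest rows permutes matrix rows identically
  man <- read.delim(manifest_path, check.names = FALSE)
  perm <- c(3L, 1L, 2L)
  man2_path <- file.path(out, "manifest_perm.tsv")
  write.table(man[perm, ], man2_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  mat2 <- build_uptake_matrix(man2_path, atlas = atl)
  expect_equal(mat2$values, mat$values[perm, ], tolerance = 1e-12)

  man$path[2L] <- file.path(out, "missing.nii.gz")
  man3_path <- file.path(out, "manifest_bad.tsv")
  write.table(man, man3_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(build_uptake_matrix(man3_path, atlas = atl), "S002")
})

test_that("the uptake matrix TSV round-trips", {
  mat <- random_matrix(6, 5, seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_uptake_matrix(mat, path)
  back <- read_uptake_matrix(path)
  expect_equal(back$values, mat$values, tolerance = 1e-12)
  expect_identical(back$subject_ids, mat$subject_ids)
  expect_equal(back$ages, mat$ages, tolerance = 1e-12)
  expect_identical(back$sexes, mat$sexes)
})

test_that("noiseless unsmoothed extraction recovers the simulated means exactly", {
  atl <- toy_atlas_12()
  cfg <- cohort_config(4, 50, 10, 20, 80, 2, noise_sd = 0,
                       global_factor_sd = 0.2, smoothing_fwhm_mm = 0, seed = 6)
  model <- ageing_model_for_atlas(atl, seed = 6)
  gen <- generate_cohort(atl, cfg, model)
  mat <- uptake_matrix_from_volumes(gen$volumes, gen$meta, atl,
                                    whole_grey_matter = FALSE)
  expect_equal(unname(mat$values), unname(gen$means), tolerance = 1e-12)
})
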