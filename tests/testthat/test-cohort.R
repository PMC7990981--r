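test_that("scanner presets reproduce the stated cohort demographics", {
  conv <- sample_cohort(cohort_preset("conventional", seed = 1))
  expect_identical(nrow(conv), 56L)
  expect_identical(sum(conv$sex == 1L), 33L)
  expect_true(all(conv$age >= 21 & conv$age <= 78))

  dig <- sample_cohort(cohort_preset("digital", seed = 1))
  expect_identical(nrow(dig), 78L)
  expect_identical(sum(dig$sex == 1L), 42L)
  expect_true(all(dig$age >= 22 & dig$age <= 87))

  expect_equal(cohort_preset("conventional")$smoothing_fwhm_mm, 8)
  expect_equal(cohort_preset("digital")$smoothing_fwhm_mm, 4)

  empty <- sample_cohort(cohort_config(0, 50, 10, 20, 80, 0, seed = 1))
  expect_identical(nrow(empty), 0L)
})

test_that("sampled ages match the truncated-normal target and the seed", {
  big <- cohort_config(10000, 58, 16, 22, 87, 5000, seed = 99)
  ages <- sample_cohort(big)$age
  expect_true(abs(mean(ages) - 58) < 1.5)

  a <- sample_cohort(cohort_preset("digital", seed = 4))
  b <- sample_cohort(cohort_preset("digital", seed = 4))
  expect_identical(a, b)
})

test_that("regional uptake follows the linear ageing formula", {
  cfg <- cohort_config(5, 50, 10, 20, 80, 2, noise_sd = 0,
                       global_factor_sd = 0, seed = 1)
  model <- ageing_model(baseline = c(A = 100), slope = c(A = -0.005),
                        reference_age = 50)
  m <- simulate_region_means(list(age = 70), model, cfg, g = 1)
  expect_equal(unname(m), 90)

  # null model: no slope, no noise, no global factor -> baseline everywhere
  null_model <- ageing_model(c(100, 80, 120), c(0, 0, 0), reference_age = 50)
  for (age in c(25, 50, 75)) {
    expect_equal(unname(simulate_region_means(list(age = age), null_model, cfg)),
                 c(100, 80, 120))
  }
})

test_that("the per-subject global factor cancels in within-subject ratios", {
  cfg <- cohort_config(5, 50, 10, 20, 80, 2, noise_sd = 0,
                       global_factor_sd = 0.5, seed = 1)
  model <- ageing_model(c(100, 80, 120), c(-0.004, -0.003, -0.002),
                        reference_age = 50)
  base <- simulate_region_means(list(age = 60), model, cfg, g = 1)
  withr::with_seed(7, {
    m <- simulate_region_means(list(age = 60), model, cfg)
  })
  expect_equal(m / m[1L], base / base[1L], tolerance = 1e-12)
})

test_that("an ageing model that goes non-positive in the age range errors", {
  cfg <- cohort_config(5, 50, 10, 20, 80, 2, seed = 1)
  steep <- ageing_model(c(100), c(-0.04), reference_age = 50)
  expect_error(simulate_region_means(list(age = 60), steep, cfg),
               "degenerate ageing model")
})

test_that("piecewise-constant rendering round-trips through ROI extraction", {
  atl <- toy_atlas_12()
  cfg <- cohort_config(3, 50, 10, 20, 80, 1, noise_sd = 0,
                       global_factor_sd = 0, smoothing_fwhm_mm = 0, seed = 1)
  means <- setNames(seq(60, 170, 10), atl$region_names)
  vol <- render_subject_volume(means, atl, cfg)
  expect_equal(extract_region_means(vol, atl), means, tolerance = 1e-12)

  # determinism along the same seed path
  cfg2 <- cohort_config(3, 50, 10, 20, 80, 1, noise_sd = 0.05,
                        smoothing_fwhm_mm = 4, seed = 1)
  v1 <- withr::with_seed(3, render_subject_volume(means, atl, cfg2))
  v2 <- withr::with_seed(3, render_subject_volume(means, atl, cfg2))
  expect_identical(v1, v2)
  # background stays masked to zero after smoothing
  expect_true(all(v1[atl$label_grid == 0L] == 0))
})

test_that("written cohorts round-trip: files, manifest, float32 volumes", {
  atl <- toy_atlas_12()
  cfg <- cohort_config(3, 50, 10, 20, 80, 1, noise_sd = 0.02,
                       smoothing_fwhm_mm = 4, seed = 5)
  model <- ageing_model_for_atlas(atl, seed = 5)
  gen <- generate_cohort(atl, cfg, model)
  out <- tempfile("cohort")
  manifest_path <- write_cohort(gen$meta, gen$volumes, out, atl$voxel_size_mm)

  man <- read.delim(manifest_path)
  expect_identical(nrow(man), 3L)
  expect_identical(length(list.files(out, pattern = "\\.nii\\.gz$")), 3L)
  expect_equal(man$age, gen$meta$age)

  back <- RNifti::readNifti(file.path(out, man$path[2L]))
  expect_equal(array(as.numeric(back), dim(back)), gen$volumes[[2L]],
               tolerance = 1e-6)

  dup <- gen$meta
  dup$subject_id <- rep("S001", 3L)
  expect_error(write_cohort(dup, gen$volumes, tempfile(), atl$voxel_size_mm),
               "collision")
})
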