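#' Configuration of a synthetic PET cohort
#'
#' Bundles the demographic and acquisition parameters of a simulated cohort:
#' sample size, the truncated-normal age distribution, the number of women,
#' the scanner's post-reconstruction Gaussian smoothing, regional noise, the
#' log-scale spread of the per-subject global scaling factor (dose and
#' scanner-sensitivity nuisance), and the seed.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param age_mean,age_sd Mean and SD of the age distribution, years.
#' @param age_min,age_max Truncation bounds, years (`age_min < age_max`).
#' @param n_women Number of subjects coded as women (<= `n_subjects`).
#' @param smoothing_fwhm_mm Scanner-resolution Gaussian FWHM, mm (>= 0).
#' @param noise_sd Regional additive noise SD as a fraction of the regional
#'   baseline.
#' @param global_factor_sd Log-scale SD of the per-subject multiplicative
#'   global factor.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @seealso [cohort_preset()] for the two bundled scanner presets.
#' @export
cohort_config <- function(n_subjects, age_mean, age_sd, age_min, age_max,
                          n_women, smoothing_fwhm_mm = 0,
                          noise_sd = 0.05, global_factor_sd = 0.15,
                          seed = 1L) {
  stopifnot(n_subjects >= 0, n_women >= 0, n_women <= n_subjects,
            age_min < age_max, age_sd > 0, smoothing_fwhm_mm >= 0,
            noise_sd >= 0, global_factor_sd >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects), age_mean = age_mean,
         age_sd = age_sd, age_min = age_min, age_max = age_max,
         n_women = as.integer(n_women),
         smoothing_fwhm_mm = smoothing_fwhm_mm, noise_sd = noise_sd,
         global_factor_sd = global_factor_sd, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Bundled scanner cohort presets
#'
#' Two presets mirror the reference healthy-control populations:
#' `"conventional"` — 56 subjects, age 50 +/- 17 years truncated to
#' \[21, 78\], 33 women, 8 mm smoothing; `"digital"` — 78 subjects, age
#' 58 +/- 16 years truncated to \[22, 87\], 42 women, 4 mm smoothing.
#'
#' @param system `"conventional"` or `"digital"`.
#' @param ... Overrides passed on to [cohort_config()] (e.g. `seed`,
#'   `noise_sd`).
#' @return A `cohort_config`.
#' @export
cohort_preset <- function(system = c("conventional", "digital"), ...) {
  system <- match.arg(system)
  base <- switch(system,
    conventional = list(n_subjects = 56, age_mean = 50, age_sd = 17,
                        age_min = 21, age_max = 78, n_women = 33,
                        smoothing_fwhm_mm = 8),
    digital = list(n_subjects = 78, age_mean = 58, age_sd = 16,
                   age_min = 22, age_max = 87, n_women = 42,
                   smoothing_fwhm_mm = 4))
  args <- utils::modifyList(base, list(...))
  do.call(cohort_config, args)
}

#' Regional linear ageing model
#'
#' Each region `k` has a positive baseline uptake `baseline_k` (arbitrary
#' units) and a fractional change per year `slope_k`; the noiseless regional
#' uptake of a subject aged `a` is
#' `baseline_k * (1 + slope_k * (a - reference_age))`.
#'
#' @param baseline Named or unnamed positive numeric vector, one per region.
#' @param slope Numeric vector of fractional changes per year, same length.
#' @param reference_age Centering age in years.
#' @return An object of class `ageing_model`.
#' @export
ageing_model <- function(baseline, slope, reference_age) {
  stopifnot(length(baseline) == length(slope), all(baseline > 0),
            is.numeric(reference_age), length(reference_age) == 1L)
  structure(list(baseline = baseline, slope = slope,
                 reference_age = reference_age),
            class = "ageing_model")
}

#' Random ageing model for an atlas, with planted stable regions
#'
#' Draws per-region baselines uniformly in `baseline_range` and fractional
#' slopes uniformly in `slope_range` (a decline of 0.2-0.7% per year by
#' default), then sets the slope of every region named in `stable_regions`
#' to exactly zero — the planted age-invariant reference the recovery tests
#' look for.
#'
#' @param atlas A [parcellation_atlas()].
#' @param slope_range Length-2 numeric, fractional change per year.
#' @param baseline_range Length-2 positive numeric, uptake units.
#' @param stable_regions Character vector of region names to pin at slope 0
#'   (silently ignored when absent from the atlas).
#' @param reference_age Centering age (years).
#' @param seed Integer seed.
#' @return An [ageing_model()] whose vectors are named by region.
#' @export
ageing_model_for_atlas <- function(atlas, slope_range = c(-0.007, -0.002),
                                   baseline_range = c(60, 140),
                                   stable_regions = "Pons",
                                   reference_age = 50, seed = 1L) {
  nr <- length(atlas$region_names)
  draws <- withr::with_seed(seed, {
    list(baseline = runif(nr, baseline_range[1L], baseline_range[2L]),
         slope = runif(nr, min(slope_range), max(slope_range)))
  })
  names(draws$baseline) <- names(draws$slope) <- atlas$region_names
  draws$slope[atlas$region_names %in% stable_regions] <- 0
  ageing_model(draws$baseline, draws$slope, reference_age)
}

#' Sample subject metadata for a cohort
#'
#' Ages are drawn from a normal distribution truncated to
#' `[age_min, age_max]` by rejection sampling; exactly `n_women` subjects
#' are coded `sex = 1` (0 = man, 1 = woman), assigned by a seeded random
#' permutation. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with columns `subject_id`, `age`, `sex`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  if (n == 0L) {
    return(data.frame(subject_id = character(0), age = numeric(0),
                      sex = integer(0)))
  }
  withr::with_seed(config$seed, {
    ages <- numeric(0)
    while (length(ages) < n) {
      draw <- rnorm(2L * n, config$age_mean, config$age_sd)
      ages <- c(ages, draw[draw >= config$age_min & draw <= config$age_max])
    }
    ages <- ages[seq_len(n)]
    sex <- integer(n)
    sex[sample.int(n, config$n_women)] <- 1L
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               age = ages, sex = sex)
  })
}

#' Simulate noiseless-to-noisy regional uptake for one subject
#'
#' Regional uptake follows
#' `m_ik = baseline_k * (1 + slope_k * (age_i - reference_age)) * g_i + eps_ik`
#' with `g_i ~ lognormal(0, global_factor_sd)` and
#' `eps_ik ~ N(0, noise_sd * baseline_k)`. Values are floored at a small
#' positive epsilon. Random draws use the current RNG state; seed the cohort
#' at a higher level (see [generate_cohort()]).
#'
#' @param meta One-row data.frame (or list) with at least `age`.
#' @param model An [ageing_model()].
#' @param config A [cohort_config()] supplying `noise_sd`,
#'   `global_factor_sd` and the admissible age range.
#' @param g Optional fixed global factor (bypasses the lognormal draw).
#' @return Named numeric vector of regional uptakes.
#' @export
simulate_region_means <- function(meta, model, config, g = NULL) {
  stopifnot(inherits(model, "ageing_model"), inherits(config, "cohort_config"))
  # the deterministic part must stay positive over the whole age range
  extremes <- c(config$age_min, config$age_max) - model$reference_age
  det_min <- pmin(1 + model$slope * extremes[1L], 1 + model$slope * extremes[2L])
  if (any(det_min <= 0)) stop_("degenerate ageing model")
  age <- meta$age
  det <- model$baseline * (1 + model$slope * (age - model$reference_age))
  if (is.null(g)) {
    g <- if (config$global_factor_sd > 0) {
      rlnorm(1L, 0, config$global_factor_sd)
    } else 1
  }
  eps <- if (config$noise_sd > 0) {
    rnorm(length(det), 0, config$noise_sd * model$baseline)
  } else 0
  m <- det * g + eps
  pmax(m, 1e-9)
}

#' Render a subject's regional uptakes into a 3-D volume
#'
#' Paints each region with its regional mean, adds independent voxel noise
#' with SD `noise_sd * regional mean * 0.5`, applies Gaussian smoothing at
#' the config's `smoothing_fwhm_mm`, and re-masks the background to zero.
#' Voxel noise uses the current RNG state.
#'
#' @param region_means Named numeric vector, one mean per atlas region.
#' @param atlas A [parcellation_atlas()].
#' @param config A [cohort_config()].
#' @return 3-D numeric array shaped like the atlas grid.
#' @export
render_subject_volume <- function(region_means, atlas, config) {
  stopifnot(length(region_means) == length(atlas$region_ids))
  labels <- atlas$label_grid
  vol <- array(0, dim = dim(labels))
  in_mask <- labels > 0L
  vol[in_mask] <- region_means[labels[in_mask]]
  if (config$noise_sd > 0) {
    sds <- config$noise_sd * region_means[labels[in_mask]] * 0.5
    vol[in_mask] <- vol[in_mask] + rnorm(sum(in_mask), 0, sds)
  }
  if (config$smoothing_fwhm_mm > 0) {
    vol <- gaussian_smooth_volume(vol, config$smoothing_fwhm_mm,
                                  atlas$voxel_size_mm)
    vol[!in_mask] <- 0
  }
  vol
}

#' Generate a full synthetic cohort
#'
#' Seeds the RNG from `config$seed`, samples metadata, simulates regional
#' uptakes per subject, and (optionally) renders one volume per subject.
#'
#' @param atlas A [parcellation_atlas()].
#' @param config A [cohort_config()].
#' @param model An [ageing_model()] covering all atlas regions.
#' @param render Render per-subject volumes? (`TRUE` by default; set `FALSE`
#'   when only the region-mean matrix is needed.)
#' @return A list with `meta` (data.frame), `means` (subjects x regions
#'   matrix) and `volumes` (list of 3-D arrays, or `NULL`).
#' @export
generate_cohort <- function(atlas, config, model, render = TRUE) {
  stopifnot(length(model$baseline) == length(atlas$region_ids))
  meta <- sample_cohort(config)
  n <- nrow(meta)
  means <- matrix(NA_real_, n, length(atlas$region_names),
                  dimnames = list(meta$subject_id, atlas$region_names))
  volumes <- if (render) vector("list", n) else NULL
  withr::with_seed(config$seed + 1000003L, {
    for (i in seq_len(n)) {
      means[i, ] <- simulate_region_means(meta[i, ], model, config)
      if (render) volumes[[i]] <- render_subject_volume(means[i, ], atlas, config)
    }
  })
  if (render) names(volumes) <- meta$subject_id
  list(meta = meta, means = means, volumes = volumes)
}

#' Write a cohort to disk (one NIfTI per subject + TSV manifest)
#'
#' @param meta Data.frame with `subject_id`, `age`, `sex`.
#' @param volumes List of 3-D arrays, one per subject, in `meta` order.
#' @param out_dir Output directory (created if needed).
#' @param voxel_size_mm Voxel size written into the NIfTI headers.
#' @return The manifest path (TSV with columns `subject_id`, `age`, `sex`,
#'   `path`), invisibly.
#' @export
write_cohort <- function(meta, volumes, out_dir, voxel_size_mm) {
  stopifnot(nrow(meta) == length(volumes))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, paste0(meta$subject_id, ".nii.gz"))
  if (anyDuplicated(paths)) {
    stop_("path collision: duplicated subject ids -> %s",
          paste(paths[duplicated(paths)], collapse = ", "))
  }
  for (i in seq_along(paths)) {
    img <- RNifti::asNifti(structure(volumes[[i]], pixdim = voxel_size_mm),
                           datatype = "float")
    RNifti::writeNifti(img, paths[i])
  }
  # paths are stored relative to the manifest so a cohort directory can move
  manifest <- data.frame(subject_id = meta$subject_id, age = meta$age,
                         sex = meta$sex, path = basename(paths))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest_path)
}
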