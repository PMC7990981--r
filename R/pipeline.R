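#' Default pipeline configuration
#'
#' A desk-scale end-to-end run: a 32 x 40 x 32 toy atlas at 4 mm voxels with
#' 12 regions (the last three named `Cerebelum_toy_L`, `Vermis_toy`, `Pons`),
#' a conventional-preset cohort, regional decline of 0.2-0.7% per year with
#' a planted age-stable pons, and a permutation-thresholded voxelwise GLM
#' comparing pons versus whole-grey-matter normalization.
#'
#' @param seed Integer master seed.
#' @param ... Named overrides of the defaults (partial lists are merged).
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    atlas = list(grid_shape = c(32L, 40L, 32L), voxel_size_mm = c(4, 4, 4),
                 n_regions = 12L),
    cohort = list(system = "conventional", noise_sd = 0.05,
                  global_factor_sd = 0.15),
    ageing = list(slope_range = c(-0.007, -0.002), baseline_range = c(60, 140),
                  stable_regions = "Pons", reference_age = 50),
    selection = list(threshold = -0.5),
    glm = list(alpha = 0.05, n_perm = 200L, connectivity = 26L,
               fixed_t = NULL, references = c("Pons", "Whole_grey_matter"))
  )
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path A `.json` or `.yaml`/`.yml` file holding (a subset of) the
#'   fields of [default_pipeline_config()]; missing fields take defaults.
#' @return A merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_("config file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_("yaml package required to read %s", path)
    }
    yaml::read_yaml(path)
  } else {
    stop_("unsupported config format: %s", path)
  }
  utils::modifyList(default_pipeline_config(), user)
}

#' Run the whole reference-selection pipeline
#'
#' Executes simulate -> extract -> grid -> score -> voxelwise GLM -> report
#' on a synthetic cohort and writes every artifact under `out_dir`:
#' `manifest.tsv` and per-subject NIfTI volumes, `uptake_matrix.tsv`,
#' `correlation_grid.tsv`, `reference_summary.tsv`, `selection.json`,
#' `tmap_<reference>.nii.gz`, `clusters_<reference>.tsv`, `report.json` and
#' a `run.json` provenance record (config, seed, package version). The run
#' is deterministic given the config (including its seed).
#'
#' @param config List from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory, created if missing.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the key in-memory results (`atlas`,
#'   `meta`, `matrix`, `summary`, `selection`, `glms`, `report`, `paths`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  say("[simulate] atlas + %s cohort (seed %d)", config$cohort$system, seed)
  atlas <- if (!is.null(config$atlas$labelmap_path)) {
    if (!file.exists(config$atlas$labelmap_path)) {
      stop_("atlas label map does not exist: %s", config$atlas$labelmap_path)
    }
    load_atlas(config$atlas$labelmap_path, config$atlas$lookup_path)
  } else {
    build_toy_atlas(config$atlas$grid_shape, config$atlas$voxel_size_mm,
                    config$atlas$n_regions, seed = seed)
  }
  cohort_args <- config$cohort
  cohort_args$system <- NULL
  cc <- do.call(cohort_preset,
                c(list(system = config$cohort$system, seed = seed),
                  cohort_args))
  model <- ageing_model_for_atlas(
    atlas, slope_range = config$ageing$slope_range,
    baseline_range = config$ageing$baseline_range,
    stable_regions = config$ageing$stable_regions,
    reference_age = config$ageing$reference_age, seed = seed)
  gen <- generate_cohort(atlas, cc, model)
  manifest <- write_cohort(gen$meta, gen$volumes, file.path(out_dir, "cohort"),
                           atlas$voxel_size_mm)
  write_atlas(atlas, file.path(out_dir, "atlas.nii.gz"),
              file.path(out_dir, "atlas_lookup.tsv"))

  say("[extract] regional means for %d subjects", nrow(gen$meta))
  mat <- build_uptake_matrix(manifest, atlas)
  write_uptake_matrix(mat, file.path(out_dir, "uptake_matrix.tsv"))

  say("[grid] %d x %d correlation grid", ncol(mat$values), ncol(mat$values))
  grid <- compute_correlation_grid(mat)
  write_correlation_grid(grid, file.path(out_dir, "correlation_grid.tsv"))
  summ <- summarize_reference(grid, system_label = config$cohort$system)
  write.table(summ, file.path(out_dir, "reference_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  say("[score] selection at median r < %s", format(config$selection$threshold))
  sel <- select_references(summ, threshold = config$selection$threshold,
                           atlas = NULL)
  jsonlite::write_json(
    list(threshold = sel$threshold, selected_regions = sel$selected_regions,
         selected_structures = sel$selected_structures,
         ranking = sel$ranking),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  say("[glm] voxelwise age model, %d permutations", config$glm$n_perm)
  mask <- atlas$label_grid > 0L
  refs <- config$glm$references
  glms <- list()
  for (ref in refs) {
    denom <- mat$values[, ref]
    vols_n <- lapply(seq_along(gen$volumes),
                     function(i) gen$volumes[[i]] / denom[i])
    res <- voxelwise_age_glm(vols_n, gen$meta, mask, atlas$voxel_size_mm,
                             alpha = config$glm$alpha,
                             n_perm = config$glm$n_perm, seed = seed,
                             fixed_t = config$glm$fixed_t,
                             connectivity = config$glm$connectivity)
    glms[[ref]] <- res
    tmap_img <- RNifti::asNifti(structure(res$tmap,
                                          pixdim = atlas$voxel_size_mm),
                                datatype = "float")
    RNifti::writeNifti(tmap_img,
                       file.path(out_dir, sprintf("tmap_%s.nii.gz", ref)))
    write.table(res$clusters,
                file.path(out_dir, sprintf("clusters_%s.tsv", ref)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("[report] comparing %d normalizations", length(glms))
  rep <- significant_volume_report(glms)
  report <- list(
    seed = seed,
    config = config,
    package_version = as.character(utils::packageVersion("petref")),
    selection = list(regions = sel$selected_regions,
                     structures = sel$selected_structures),
    volumes = setNames(as.list(rep$total_significant_mm3), rep$reference),
    t_max = setNames(as.list(rep$t_max), rep$reference),
    fold_vs_top = setNames(as.list(rep$fold_vs_top), rep$reference),
    top_reference = attr(rep, "top"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(atlas = atlas, meta = gen$meta, matrix = mat,
                 summary = summ, selection = sel, glms = glms, report = rep,
                 paths = list(out_dir = out_dir, manifest = manifest,
                              report = file.path(out_dir, "report.json"))))
}
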