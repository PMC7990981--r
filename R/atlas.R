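#' Labelled brain parcellations
#'
#' A `parcellation_atlas` holds an integer label volume (0 = outside the
#' brain), the ordered region ids and names, the voxel size in millimetres,
#' and a total map from region name to anatomical structure. Regions are
#' pairwise disjoint by construction of the label grid, and every non-zero
#' label in the grid appears in `region_ids` (and vice versa).
#'
#' @param label_grid 3-D integer array of region labels; 0 marks background.
#' @param region_names Character vector, one name per positive label
#'   `1..max(label_grid)` in id order (AAL-style strings such as
#'   `"Cerebelum_8_L"` or `"Pons"`).
#' @param voxel_size_mm Positive numeric triple, voxel edge lengths in mm.
#' @param structure_of Optional named character vector mapping every region
#'   name to a structure name; defaults to [map_to_structure()] applied to
#'   each region name.
#' @return An object of class `parcellation_atlas` with fields `label_grid`,
#'   `region_ids`, `region_names`, `voxel_size_mm`, `structure_of`.
#' @seealso [build_toy_atlas()], [load_atlas()], [map_to_structure()]
#' @export
parcellation_atlas <- function(label_grid, region_names, voxel_size_mm,
                               structure_of = NULL) {
  stopifnot(length(dim(label_grid)) == 3L)
  storage.mode(label_grid) <- "integer"
  labels <- sort(unique(label_grid[label_grid > 0L]))
  region_ids <- seq_along(region_names)
  if (!setequal(labels, region_ids)) {
    missing_in_grid <- setdiff(region_ids, labels)
    orphan <- setdiff(labels, region_ids)
    if (length(orphan)) {
      stop_("label(s) present in grid but absent from lookup: %s",
            paste(orphan, collapse = ", "))
    }
    stop_("region id(s) with no voxels in grid: %s",
          paste(missing_in_grid, collapse = ", "))
  }
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (anyDuplicated(region_names)) stop_("duplicated region names")
  if (is.null(structure_of)) {
    structure_of <- vapply(region_names, map_to_structure, character(1L))
  } else {
    if (!all(region_names %in% names(structure_of))) {
      stop_("structure_of is not total over region names")
    }
    structure_of <- structure_of[region_names]
  }
  structure(
    list(label_grid = label_grid,
         region_ids = as.integer(region_ids),
         region_names = as.character(region_names),
         voxel_size_mm = as.numeric(voxel_size_mm),
         structure_of = structure_of),
    class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("parcellation_atlas: %d regions, grid %s, voxel %s mm\n",
              length(x$region_ids), paste(dim(x$label_grid), collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  cat(sprintf("  brain mask: %d voxels; structures: %d\n",
              sum(x$label_grid > 0L), length(unique(x$structure_of))))
  invisible(x)
}

#' Map a region name to its anatomical structure
#'
#' Fine atlas regions are gathered into the structure they belong to when
#' feasible: any name with prefix `"Cerebelum_"` or `"Vermis_"` (cerebellar
#' lobes and vermis) maps to `"cerebellum"`, `"Pons"` maps to `"pons"`, and
#' every other region maps to itself (identity grouping).
#'
#' @param region_name Character scalar region name.
#' @param atlas Optional [parcellation_atlas()]; when supplied the name must
#'   belong to the atlas and the atlas's own `structure_of` map is used.
#' @return Character scalar structure name.
#' @examples
#' map_to_structure("Cerebelum_8_L")  # "cerebellum"
#' map_to_structure("Vermis_8")       # "cerebellum"
#' map_to_structure("Pons")           # "pons"
#' map_to_structure("Frontal_Sup_R")  # itself
#' @export
map_to_structure <- function(region_name, atlas = NULL) {
  stopifnot(is.character(region_name), length(region_name) == 1L)
  if (!is.null(atlas)) {
    if (!region_name %in% atlas$region_names) {
      stop_("unknown region name: %s", region_name)
    }
    return(unname(atlas$structure_of[region_name]))
  }
  if (startsWith(region_name, "Cerebelum_") || startsWith(region_name, "Vermis_")) {
    return("cerebellum")
  }
  if (region_name == "Pons") return("pons")
  region_name
}

# region names that must not contribute to the whole-grey-matter union
is_brainstem_name <- function(nm) {
  nm %in% c("Pons", "Midbrain", "Medulla") | startsWith(nm, "Brainstem")
}

#' Generate a procedural toy atlas
#'
#' Builds an ellipsoidal brain mask centred in the grid and partitions it
#' into `n_regions` contiguous regions by nearest-centroid growth from
#' uniformly sampled in-mask seed voxels (deterministic given `seed`).
#' Regions are named `"R001"`, `"R002"`, ...; when `n_regions >= 10` the
#' last three regions are renamed `"Cerebelum_toy_L"`, `"Vermis_toy"` and
#' `"Pons"` so that structure grouping is exercised.
#'
#' @param grid_shape Integer triple, each >= 8.
#' @param voxel_size_mm Positive numeric triple (mm).
#' @param n_regions Number of regions, >= 1 and at most the mask voxel count.
#' @param seed Integer seed controlling seed-voxel placement.
#' @return A [parcellation_atlas()].
#' @examples
#' atl <- build_toy_atlas(c(16, 16, 16), c(4, 4, 4), n_regions = 4, seed = 1)
#' table(atl$label_grid[atl$label_grid > 0])
#' @export
build_toy_atlas <- function(grid_shape, voxel_size_mm, n_regions, seed) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            n_regions >= 1L, length(voxel_size_mm) == 3L)
  grid_shape <- as.integer(grid_shape)
  centre <- (grid_shape + 1) / 2
  semi <- (grid_shape - 1) / 2 * 0.85
  i <- seq_len(grid_shape[1L]); j <- seq_len(grid_shape[2L]); k <- seq_len(grid_shape[3L])
  d2 <- outer(outer(((i - centre[1L]) / semi[1L])^2,
                    ((j - centre[2L]) / semi[2L])^2, `+`),
              ((k - centre[3L]) / semi[3L])^2, `+`)
  mask <- d2 <= 1
  in_mask <- which(mask)
  if (n_regions > length(in_mask)) stop_("atlas oversegmented")

  labels <- array(0L, dim = grid_shape)
  if (n_regions == 1L) {
    labels[in_mask] <- 1L
  } else {
    seeds <- withr::with_seed(seed, sample(in_mask, n_regions))
    coords <- lin_to_ijk(in_mask, grid_shape)
    seed_xyz <- lin_to_ijk(seeds, grid_shape)
    # nearest seed in voxel coordinates; ties -> lowest region id
    best_d <- rep(Inf, length(in_mask))
    best_r <- integer(length(in_mask))
    for (r in seq_len(n_regions)) {
      dr <- (coords[, 1L] - seed_xyz[r, 1L])^2 +
            (coords[, 2L] - seed_xyz[r, 2L])^2 +
            (coords[, 3L] - seed_xyz[r, 3L])^2
      upd <- dr < best_d
      best_d[upd] <- dr[upd]
      best_r[upd] <- r
    }
    labels[in_mask] <- best_r
  }

  nms <- sprintf("R%03d", seq_len(n_regions))
  if (n_regions >= 10L) {
    nms[n_regions - 2L] <- "Cerebelum_toy_L"
    nms[n_regions - 1L] <- "Vermis_toy"
    nms[n_regions] <- "Pons"
  }
  parcellation_atlas(labels, nms, voxel_size_mm)
}

#' Write an atlas to disk as NIfTI + TSV lookup
#'
#' @param atlas A [parcellation_atlas()].
#' @param labelmap_path Output NIfTI path for the label grid.
#' @param lookup_path Output TSV path with header `id`, `name`, `structure`.
#' @return Invisibly, the two paths.
#' @export
write_atlas <- function(atlas, labelmap_path, lookup_path) {
  img <- RNifti::asNifti(structure(atlas$label_grid,
                                   pixdim = atlas$voxel_size_mm),
                         datatype = "int32")
  RNifti::writeNifti(img, labelmap_path)
  lut <- data.frame(id = atlas$region_ids,
                    name = atlas$region_names,
                    structure = unname(atlas$structure_of))
  write.table(lut, lookup_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(labelmap_path, lookup_path))
}

#' Load an atlas from a NIfTI label map and a TSV lookup
#'
#' The lookup must have columns `id` and `name`; a `structure` column is
#' optional and defaults to [map_to_structure()] of each region name. Labels
#' in the grid are cross-checked against the lookup and orphan labels are an
#' error. The voxel size is read from the NIfTI header.
#'
#' @param labelmap_path NIfTI file with integer labels (0 = background).
#' @param lookup_path TSV file with header `id`, `name`[, `structure`].
#' @return A [parcellation_atlas()].
#' @export
load_atlas <- function(labelmap_path, lookup_path) {
  img <- RNifti::readNifti(labelmap_path)
  vox <- RNifti::pixdim(img)[1:3]
  grid <- array(as.integer(round(as.array(img))), dim = dim(img))
  lut <- read.delim(lookup_path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(lut))) {
    stop_("lookup must have columns id and name")
  }
  lut <- lut[order(lut$id), , drop = FALSE]
  if (!identical(as.integer(lut$id), seq_len(nrow(lut)))) {
    stop_("lookup ids must be consecutive 1-based integers")
  }
  labels_in_grid <- sort(unique(grid[grid > 0L]))
  orphan <- setdiff(labels_in_grid, lut$id)
  if (length(orphan)) {
    stop_("label(s) present in grid but absent from lookup: %s",
          paste(orphan, collapse = ", "))
  }
  structure_of <- NULL
  if ("structure" %in% names(lut)) {
    structure_of <- setNames(as.character(lut$structure), lut$name)
  }
  parcellation_atlas(grid, lut$name, vox, structure_of = structure_of)
}
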