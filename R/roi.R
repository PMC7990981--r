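#' Subjects-by-regions uptake matrix
#'
#' Container for the regional mean-uptake matrix the normalization grid
#' operates on: a subjects x regions numeric matrix plus subject ids, ages
#' and sex codes carried from the manifest.
#'
#' @param values Numeric matrix, subjects x regions, all entries finite.
#' @param subject_ids Character vector, one per row.
#' @param region_names Character vector, one per column.
#' @param ages Numeric vector of ages (years), one per row.
#' @param sexes Integer vector (0 = man, 1 = woman), one per row.
#' @return An object of class `uptake_matrix`.
#' @export
uptake_matrix <- function(values, subject_ids, region_names, ages, sexes) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(subject_ids),
            ncol(values) == length(region_names),
            length(ages) == length(subject_ids),
            length(sexes) == length(subject_ids),
            all(is.finite(values)))
  dimnames(values) <- list(subject_ids, region_names)
  structure(list(values = values, subject_ids = as.character(subject_ids),
                 region_names = as.character(region_names),
                 ages = as.numeric(ages), sexes = as.integer(sexes)),
            class = "uptake_matrix")
}

#' @export
print.uptake_matrix <- function(x, ...) {
  cat(sprintf("uptake_matrix: %d subjects x %d regions (age %.1f-%.1f y, %d women)\n",
              nrow(x$values), ncol(x$values), min(x$ages), max(x$ages),
              sum(x$sexes == 1L)))
  invisible(x)
}

#' Mean uptake of each atlas region in one volume
#'
#' Unweighted arithmetic mean of the voxel values within each region's
#' label set. When `whole_grey_matter = TRUE` an extra entry
#' `"Whole_grey_matter"` is appended, computed over the union of all
#' non-brainstem regions (the proportional-scaling global reference).
#'
#' @param volume 3-D numeric array, same shape as the atlas grid.
#' @param atlas A [parcellation_atlas()].
#' @param whole_grey_matter Append the grey-matter union entry?
#' @return Named numeric vector of regional means.
#' @export
extract_region_means <- function(volume, atlas, whole_grey_matter = FALSE) {
  if (!identical(dim(volume), dim(atlas$label_grid))) {
    stop_("volume shape %s does not match atlas grid %s",
          paste(dim(volume), collapse = "x"),
          paste(dim(atlas$label_grid), collapse = "x"))
  }
  labels <- atlas$label_grid
  in_mask <- labels > 0L
  lab <- labels[in_mask]
  vals <- volume[in_mask]
  sums <- rowsum(vals, lab)
  counts <- tabulate(lab, nbins = length(atlas$region_ids))
  if (any(counts == 0L)) {
    stop_("empty region(s): %s",
          paste(atlas$region_names[counts == 0L], collapse = ", "))
  }
  means <- setNames(as.numeric(sums) / counts, atlas$region_names)
  if (whole_grey_matter) {
    gm <- !is_brainstem_name(atlas$region_names)[lab]
    means <- c(means, Whole_grey_matter = mean(vals[gm]))
  }
  means
}

#' Build the uptake matrix from a cohort manifest
#'
#' Reads each subject volume named in the manifest (in manifest row order),
#' extracts regional means against the atlas, and carries ages and sexes
#' over.
#'
#' @param manifest_path TSV with columns `subject_id`, `age`, `sex`, `path`.
#' @param atlas A [parcellation_atlas()].
#' @param whole_grey_matter Append the `"Whole_grey_matter"` union region
#'   (default `TRUE`, giving the full candidate-reference universe).
#' @return An [uptake_matrix()].
#' @export
build_uptake_matrix <- function(manifest_path, atlas, whole_grey_matter = TRUE) {
  man <- read.delim(manifest_path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "age", "sex", "path") %in% names(man)))
  rows <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    # non-absolute paths resolve against the manifest's own directory
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(dirname(manifest_path), p)
    if (!file.exists(p)) {
      stop_("volume for subject %s is unreadable: %s", man$subject_id[i], p)
    }
    vol <- as.array(RNifti::readNifti(p))
    extract_region_means(vol, atlas, whole_grey_matter = whole_grey_matter)
  })
  uptake_matrix(do.call(rbind, rows), man$subject_id,
                names(rows[[1L]]), man$age, man$sex)
}

#' Uptake matrix straight from in-memory volumes
#'
#' In-memory counterpart of [build_uptake_matrix()] for cohorts produced by
#' [generate_cohort()].
#'
#' @param volumes List of 3-D arrays in `meta` row order.
#' @param meta Data.frame with `subject_id`, `age`, `sex`.
#' @param atlas A [parcellation_atlas()].
#' @param whole_grey_matter Append the grey-matter union region?
#' @return An [uptake_matrix()].
#' @export
uptake_matrix_from_volumes <- function(volumes, meta, atlas,
                                       whole_grey_matter = TRUE) {
  stopifnot(length(volumes) == nrow(meta))
  rows <- lapply(volumes, extract_region_means, atlas = atlas,
                 whole_grey_matter = whole_grey_matter)
  uptake_matrix(do.call(rbind, rows), meta$subject_id,
                names(rows[[1L]]), meta$age, meta$sex)
}

#' Serialize / read an uptake matrix as TSV
#'
#' Columns: `subject_id`, `age`, `sex`, then one column per region. Region
#' names are preserved exactly via a header comment-free TSV with
#' `check.names = FALSE`.
#'
#' @param x An [uptake_matrix()].
#' @param path Output (or input) TSV path.
#' @return `write_uptake_matrix`: the path, invisibly.
#'   `read_uptake_matrix`: an [uptake_matrix()].
#' @export
write_uptake_matrix <- function(x, path) {
  stopifnot(inherits(x, "uptake_matrix"))
  df <- data.frame(subject_id = x$subject_ids, age = x$ages, sex = x$sexes,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_uptake_matrix
#' @export
read_uptake_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  stopifnot(all(c("subject_id", "age", "sex") %in% names(df)))
  regions <- setdiff(names(df), c("subject_id", "age", "sex"))
  uptake_matrix(as.matrix(df[regions]), df$subject_id, regions,
                df$age, df$sex)
}
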