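#' Normalize an uptake matrix by a reference region (SUVr)
#'
#' Divides every subject's row by that subject's uptake in the reference
#' region, so the reference column becomes identically 1 and every other
#' column is a standardized uptake value ratio (SUVr). Any per-subject
#' multiplicative global factor cancels exactly.
#'
#' @param x An [uptake_matrix()].
#' @param reference Region name to use as the denominator.
#' @return An [uptake_matrix()] of SUVr values.
#' @export
normalize_by_reference <- function(x, reference) {
  stopifnot(inherits(x, "uptake_matrix"))
  if (!reference %in% x$region_names) {
    stop_("unknown reference region: %s", reference)
  }
  ref <- x$values[, reference]
  bad <- which(ref <= 0)
  if (length(bad)) {
    stop_("non-positive reference value in %s for subject(s): %s", reference,
          paste(x$subject_ids[bad], collapse = ", "))
  }
  uptake_matrix(x$values / ref, x$subject_ids, x$region_names, x$ages,
                x$sexes)
}

# constant up to floating-point jitter (e.g. a ratio of identically scaled
# rows): correlation is undefined, not a number
effectively_constant <- function(x) {
  r <- range(x)
  (r[2L] - r[1L]) <= 1e-9 * max(abs(r[1L]), abs(r[2L]), 1e-300)
}

#' Pearson correlation of a regional measure with age
#'
#' Standard product-moment coefficient. A constant `x` (or constant `ages`)
#' has no defined correlation and yields `NA` rather than a number.
#'
#' @param x Numeric vector of regional values, one per subject.
#' @param ages Numeric vector of ages, same length, length >= 3.
#' @return The correlation coefficient, or `NA` when undefined.
#' @export
pearson_with_age <- function(x, ages) {
  if (length(x) != length(ages)) stop_("length mismatch: x vs ages")
  if (length(x) < 3L) stop_("need at least 3 subjects")
  if (effectively_constant(x) || effectively_constant(ages)) return(NA_real_)
  cor(x, ages)
}

#' Reference-by-target grid of age correlations
#'
#' For every candidate reference region the uptake matrix is normalized by
#' that region and the Pearson correlation of every target region's SUVr
#' with age is computed: entry `[ref, target]` of the grid. The diagonal
#' (reference = target, SUVr constant 1) is undefined and stored as `NA`,
#' as is any other constant SUVr column.
#'
#' @param x An [uptake_matrix()] with >= 3 subjects.
#' @return An object of class `correlation_grid`: list with `r` (reference x
#'   target matrix), `reference_names`, `target_names`, `n_subjects`.
#' @export
compute_correlation_grid <- function(x) {
  stopifnot(inherits(x, "uptake_matrix"))
  n <- nrow(x$values)
  if (n < 3L) stop_("need at least 3 subjects")
  regions <- x$region_names
  nr <- length(regions)
  r <- matrix(NA_real_, nr, nr, dimnames = list(regions, regions))
  ages <- x$ages
  age_ok <- !effectively_constant(ages)
  for (ref in seq_len(nr)) {
    suvr <- normalize_by_reference(x, regions[ref])$values
    ok <- !apply(suvr, 2L, effectively_constant) & age_ok
    if (any(ok)) {
      r[ref, ok] <- suppressWarnings(cor(suvr[, ok, drop = FALSE], ages))
    }
    r[ref, ref] <- NA_real_
  }
  structure(list(r = r, reference_names = regions, target_names = regions,
                 n_subjects = n),
            class = "correlation_grid")
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat(sprintf("correlation_grid: %d references x %d targets, n = %d (%d undefined entries)\n",
              length(x$reference_names), length(x$target_names),
              x$n_subjects, sum(is.na(x$r))))
  invisible(x)
}

#' Per-reference summary of the correlation grid
#'
#' For each reference region: the median of the defined target correlations
#' (average-of-two for even counts) and the strongest coefficient, read as
#' the minimum signed value, i.e. the most negative correlation with age.
#'
#' @param grid A [compute_correlation_grid()] result.
#' @param system_label Optional label naming the PET system the grid came
#'   from (carried into the summary for reporting).
#' @return A data.frame of class `normalization_summary` with columns
#'   `region`, `strongest_r`, `median_r` and attribute `system_label`.
#' @export
summarize_reference <- function(grid, system_label = "") {
  stopifnot(inherits(grid, "correlation_grid"))
  rows <- lapply(seq_along(grid$reference_names), function(i) {
    vals <- grid$r[i, ]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      stop_("reference %s has no defined correlation entries",
            grid$reference_names[i])
    }
    data.frame(region = grid$reference_names[i],
               strongest_r = min(vals), median_r = median(vals))
  })
  out <- do.call(rbind, rows)
  attr(out, "system_label") <- system_label
  class(out) <- c("normalization_summary", "data.frame")
  out
}

#' Write a correlation grid as TSV
#'
#' @param grid A `correlation_grid`.
#' @param path Output TSV path (references as rows, targets as columns;
#'   undefined entries written as `NA`).
#' @return The path, invisibly.
#' @export
write_correlation_grid <- function(grid, path) {
  df <- data.frame(reference = grid$reference_names, grid$r,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
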