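# internal helpers shared across modules

# FWHM of a Gaussian kernel -> sigma, in the units of `fwhm`
# (optionally per-axis voxel units when voxel sizes are supplied)
#' Convert a Gaussian FWHM to its standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, optionally divided by the voxel
#' size of each axis so the result is in voxel units.
#'
#' @param fwhm_mm Full width at half maximum, millimetres. Must be >= 0.
#' @param voxel_size_mm Optional voxel size (scalar or per-axis triple, mm).
#'   When given, the returned sigma is per-axis in voxel units.
#' @return Numeric sigma (same length as `voxel_size_mm` when supplied).
#' @examples
#' fwhm_to_sigma(8)          # mm
#' fwhm_to_sigma(8, c(4, 4, 4))  # voxels per axis
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm = NULL) {
  stopifnot(is.numeric(fwhm_mm), length(fwhm_mm) == 1L, fwhm_mm >= 0)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  if (!is.null(voxel_size_mm)) {
    stopifnot(all(voxel_size_mm > 0))
    sigma <- sigma / voxel_size_mm
  }
  sigma
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# array index (i, j, k) helpers for 3-D lattices stored as R arrays
lin_to_ijk <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1L]
  j <- (idx0 %/% dim[1L]) %% dim[2L]
  k <- idx0 %/% (dim[1L] * dim[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_lin <- function(ijk, dim) {
  (ijk[, 3L] - 1L) * dim[1L] * dim[2L] + (ijk[, 2L] - 1L) * dim[1L] + ijk[, 1L]
}
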