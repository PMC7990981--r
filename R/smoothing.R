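#' Separable Gaussian smoothing of a 3-D volume
#'
#' Convolves the volume along each axis with a discrete Gaussian kernel of
#' standard deviation `sigma_axis = fwhm_mm / (2 sqrt(2 log 2)) / voxel_size_axis`
#' voxels. Each 1-D kernel is truncated at 4 sigma and renormalized to sum to
#' one, so a unit impulse away from the boundary keeps total mass 1 and a
#' constant field is an eigenfunction (interior voxels unchanged). Values
#' outside the grid are treated as zero. `fwhm_mm = 0` is the identity.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm Full width at half maximum of the kernel, mm, >= 0.
#' @param voxel_size_mm Positive numeric triple (mm per axis).
#' @return A 3-D numeric array of the same shape.
#' @examples
#' v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 1
#' sum(gaussian_smooth_volume(v, 8, c(4, 4, 4)))  # 1
#' @export
gaussian_smooth_volume <- function(volume, fwhm_mm, voxel_size_mm) {
  stopifnot(length(dim(volume)) == 3L, length(voxel_size_mm) == 3L,
            all(voxel_size_mm > 0))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop_("fwhm_mm must be a single non-negative number")
  }
  if (fwhm_mm == 0) return(volume)
  sigmas <- fwhm_to_sigma(fwhm_mm, voxel_size_mm)
  out <- volume
  for (ax in 1:3) out <- convolve_axis(out, gaussian_kernel(sigmas[ax]), ax)
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# zero-padded 1-D convolution along axis `ax` of a 3-D array
convolve_axis <- function(vol, kernel, ax) {
  d <- dim(vol)
  perm <- switch(ax, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  v <- aperm(vol, perm)
  dm <- dim(v)
  m <- matrix(v, nrow = dm[1L])
  n <- dm[1L]
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (o in seq_along(kernel)) {
    shift <- o - r - 1L   # kernel offset
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kernel[o] * m[src[ok], ]
  }
  aperm(array(out, dm), order(perm))
}
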