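#' Compare significant cluster volumes across normalizations
#'
#' Summarizes, per reference region used for intensity normalization, the
#' total significant cluster volume (mm3) and the global t maximum, and
#' reports the fold-ratio of the top reference (largest total volume)
#' against every other reference.
#'
#' @param results Either a named list of [voxelwise_age_glm()] results, or a
#'   named numeric vector of total significant volumes (mm3); needs >= 2
#'   normalizations.
#' @param t_max Optional named numeric vector of global t maxima (used with
#'   the numeric-vector form).
#' @return data.frame of class `volume_report` with columns `reference`,
#'   `total_significant_mm3`, `t_max`, `fold_vs_top` (top reference's volume
#'   divided by this one's; 1 for the top itself), sorted by descending
#'   volume. The top reference name is attached as attribute `"top"`.
#' @examples
#' significant_volume_report(
#'   c(pons = 143330, cerebellum = 84216, whole_grey_matter = 41528))
#' @export
significant_volume_report <- function(results, t_max = NULL) {
  if (is.list(results) && all(vapply(results, inherits, logical(1L),
                                     "glm_result"))) {
    vols <- vapply(results, function(r) r$total_significant_mm3, numeric(1L))
    tmx <- vapply(results, function(r) r$t_max, numeric(1L))
  } else {
    vols <- unlist(results)
    tmx <- if (is.null(t_max)) rep(NA_real_, length(vols)) else t_max[names(vols)]
  }
  if (length(vols) < 2L) stop_("need at least 2 normalizations to compare")
  if (is.null(names(vols)) || any(!nzchar(names(vols)))) {
    stop_("normalizations must be named")
  }
  ord <- order(-vols, names(vols))
  vols <- vols[ord]
  tmx <- tmx[ord]
  top <- vols[1L]
  out <- data.frame(reference = names(vols),
                    total_significant_mm3 = as.numeric(vols),
                    t_max = as.numeric(tmx),
                    fold_vs_top = as.numeric(top / vols))
  rownames(out) <- NULL
  attr(out, "top") <- names(vols)[1L]
  class(out) <- c("volume_report", "data.frame")
  out
}
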