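neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  ord <- abs(g$di) + abs(g$dj) + abs(g$dk)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1L, "18" = ord <= 2L, "26" = rep(TRUE, nrow(g)),
                 stop_("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, , drop = FALSE])
}

#' Label supra-threshold clusters in a t-map
#'
#' Connected components of `{t >= threshold}` under 26-connectivity by
#' default (voxels sharing a face, edge or corner belong to one cluster).
#' Components are found by a vectorized breadth-first flood fill. Clusters
#' are returned sorted by descending volume; the peak is the voxel with the
#' largest t (ties broken by lowest linear index). `+Inf` t values sort
#' above any finite threshold.
#'
#' @param tmap 3-D numeric array of t statistics.
#' @param threshold_T Finite cluster-forming threshold (`t >= threshold_T`).
#' @param voxel_size_mm Numeric triple; cluster volume is
#'   `n_voxels * prod(voxel_size_mm)` exactly.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return data.frame with columns `id`, `n_voxels`, `volume_mm3`, `t_max`,
#'   `peak_i`, `peak_j`, `peak_k`; zero rows when nothing is supra-threshold.
#' @export
label_clusters <- function(tmap, threshold_T, voxel_size_mm,
                           connectivity = 26L) {
  stopifnot(length(dim(tmap)) == 3L, is.finite(threshold_T),
            length(voxel_size_mm) == 3L)
  d <- dim(tmap)
  supra <- which(tmap >= threshold_T)
  empty <- data.frame(id = integer(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), t_max = numeric(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0))
  if (!length(supra)) return(empty)

  offs <- neighbor_offsets(connectivity)
  in_set <- array(FALSE, dim = d)
  in_set[supra] <- TRUE
  labels <- array(0L, dim = d)
  next_id <- 0L
  for (s in supra) {
    if (labels[s] != 0L) next
    next_id <- next_id + 1L
    labels[s] <- next_id
    frontier <- s
    while (length(frontier)) {
      ijk <- lin_to_ijk(frontier, d)
      cand <- vector("list", nrow(offs))
      for (o in seq_len(nrow(offs))) {
        nb <- cbind(ijk[, 1L] + offs[o, 1L], ijk[, 2L] + offs[o, 2L],
                    ijk[, 3L] + offs[o, 3L])
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
              nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
              nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
        cand[[o]] <- ijk_to_lin(nb[ok, , drop = FALSE], d)
      }
      cand <- unique(unlist(cand))
      cand <- cand[in_set[cand] & labels[cand] == 0L]
      labels[cand] <- next_id
      frontier <- cand
    }
  }

  vox_vol <- prod(voxel_size_mm)
  rows <- lapply(seq_len(next_id), function(id) {
    members <- which(labels == id)
    tv <- tmap[members]
    peak <- members[which.max(tv)]   # which.max: first (lowest index) on ties
    pk <- lin_to_ijk(peak, d)
    data.frame(id = id, n_voxels = length(members),
               volume_mm3 = length(members) * vox_vol, t_max = max(tv),
               peak_i = pk[1L], peak_j = pk[2L], peak_k = pk[3L])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$volume_mm3, out$id), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
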