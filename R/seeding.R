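#' Automatic seed placement at a region's centre of mass
#'
#' Places a fixed-size seed in one atlas region under two constraints: all
#' seed voxels lie inside the region, and all lie on the region's central
#' plane — the z-slice nearest (in mm) to the region's centre-of-mass z
#' coordinate that contains at least one region voxel, ties broken toward
#' the lower slice. The native acquisition grid is typically much coarser in
#' z (slice thickness), which motivates restricting the seed to one slice.
#' The anchor is the in-plane region voxel nearest (Euclidean, mm-scaled) to
#' the centre of mass; the remaining `seed_size - 1` voxels are the next
#' nearest in-plane region voxels, distance ties broken by lexicographic
#' voxel coordinate. A region with fewer in-plane voxels than `seed_size`
#' yields all of them, with `truncated = TRUE`.
#'
#' @param atlas A `label_atlas`.
#' @param region_id Region to seed.
#' @param seed_size Number of seed voxels (default 5).
#' @return A `seed_set`: list with `region_id`, `voxels` (n x 3 integer
#'   matrix), `centroid` (centre of mass, voxel units), `plane` (z index),
#'   `truncated` flag.
#' @export
place_seed <- function(atlas, region_id, seed_size = 5L) {
  vox <- voxel_coords(atlas$labels == region_id)
  if (nrow(vox) == 0L)
    stop("region ", region_id, " not present in atlas", call. = FALSE)
  vs <- atlas$voxel_size
  com <- colMeans(vox)
  zs <- sort(unique(vox[, 3]))
  # round distances so exact geometric ties are not broken by floating-point
  # noise (keeps placement translation-equivariant)
  dz <- round(abs(zs - com[3]) * vs[3], 9)
  plane <- zs[which.min(dz)]  # which.min takes the first = lower slice on ties
  on_plane <- vox[vox[, 3] == plane, , drop = FALSE]
  d2 <- round(((on_plane[, 1] - com[1]) * vs[1])^2 +
              ((on_plane[, 2] - com[2]) * vs[2])^2 +
              ((on_plane[, 3] - com[3]) * vs[3])^2, 9)
  ord <- order(d2, on_plane[, 1], on_plane[, 2], on_plane[, 3])
  n_take <- min(seed_size, nrow(on_plane))
  truncated <- n_take < seed_size
  if (truncated)
    warning(sprintf("region %d has %d voxel(s) on its central plane (< %d)",
                    region_id, nrow(on_plane), seed_size), call. = FALSE)
  structure(
    list(region_id = as.integer(region_id),
         voxels = on_plane[ord[seq_len(n_take)], , drop = FALSE],
         centroid = com, plane = as.integer(plane), truncated = truncated),
    class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("Seed for region %d: %d voxel(s) on plane z=%d%s\n",
              x$region_id, nrow(x$voxels), x$plane,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Place seeds in every atlas region
#'
#' @param atlas A `label_atlas`.
#' @param seed_size Voxels per seed (default 5).
#' @return Named list of `seed_set`, one per region id `1..R`.
#' @export
place_all_seeds <- function(atlas, seed_size = 5L) {
  ids <- seq_len(n_regions(atlas))
  out <- lapply(ids, function(i) place_seed(atlas, i, seed_size))
  names(out) <- ids
  out
}

#' Mean time-course over a seed's voxels
#'
#' @param series A `bold_series` on the atlas grid.
#' @param seed A `seed_set`.
#' @return Numeric vector of length t (unweighted voxel mean per time point).
#' @export
seed_timecourse <- function(series, seed) {
  d <- dim(series$data)
  idx <- seed$voxels[, 1] +
    (seed$voxels[, 2] - 1L) * d[1] +
    (seed$voxels[, 3] - 1L) * d[1] * d[2]
  if (!all(series$brain_mask[idx]))
    stop("seed voxel outside the brain mask", call. = FALSE)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  colMeans(m[idx, , drop = FALSE])
}

#' Export a seed table
#' @param seeds List of `seed_set` from [place_all_seeds()].
#' @return Data.frame with region, x, y, z, plane, truncated.
#' @export
seed_table <- function(seeds) {
  do.call(rbind, lapply(seeds, function(s)
    data.frame(region = s$region_id, x = s$voxels[, 1], y = s$voxels[, 2],
               z = s$voxels[, 3], plane = s$plane, truncated = s$truncated)))
}
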