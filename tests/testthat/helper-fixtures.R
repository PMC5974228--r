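# Fixture builders shared by the test files. Everything is generated in
# code; no binary fixtures.

# Atlas from explicit rectangular blocks: `blocks` is a list of
# list(x = a:b, y = c:d, z = e:f) region extents, labelled 1..length.
box_atlas <- function(blocks, shape, voxel_size = c(1, 1, 1)) {
  lab <- array(0L, dim = shape)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    lab[b$x, b$y, b$z] <- i
  }
  label_atlas(lab, voxel_size = voxel_size)
}

# Two-region single-slice atlas on a 6x3x1-ish grid, handy for seed tests.
two_region_atlas <- function() {
  box_atlas(list(list(x = 1:3, y = 1:3, z = 1:2),
                 list(x = 4:6, y = 1:3, z = 1:2)),
            shape = c(6, 3, 2))
}

# BOLD series with prescribed region time-courses: every voxel of region i
# carries exactly tc[, i] (no voxel noise), so correlation oracles are exact.
bold_from_region_tcs <- function(atlas, tc, tr = 2) {
  d <- dim(atlas$labels)
  n_t <- nrow(tc)
  m <- matrix(0, prod(d), n_t)
  for (i in seq_len(n_regions(atlas))) {
    idx <- which(atlas$labels == i)
    m[idx, ] <- matrix(tc[, i], length(idx), n_t, byrow = TRUE)
  }
  bold_series(array(m, dim = c(d, n_t)), tr = tr,
              voxel_size = atlas$voxel_size,
              brain_mask = atlas$labels > 0L)
}

# BOLD series from explicit per-voxel time-courses (t x V over mask order).
bold_from_voxel_tcs <- function(atlas, tc, tr = 2) {
  d <- dim(atlas$labels)
  mask <- atlas$labels > 0L
  m <- matrix(0, prod(d), nrow(tc))
  m[which(mask), ] <- t(tc)
  bold_series(array(m, dim = c(d, nrow(tc))), tr = tr,
              voxel_size = atlas$voxel_size, brain_mask = mask)
}

# Flood-fill check that a region's voxels form one face-connected component.
region_is_contiguous <- function(atlas, region_id) {
  vox <- which(atlas$labels == region_id, arr.ind = TRUE)
  n <- nrow(vox)
  if (n <= 1L) return(TRUE)
  key <- paste(vox[, 1], vox[, 2], vox[, 3])
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (o in seq_len(6)) {
      nb <- match(paste(vox[v, 1] + offs[o, 1], vox[v, 2] + offs[o, 2],
                        vox[v, 3] + offs[o, 3]), key)
      if (!is.na(nb) && !seen[nb]) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  all(seen)
}

# Null difference matrices for n subjects over an R-node symmetric universe.
null_diffs <- function(n_subjects, n_nodes, sd = 0.1, group = "control",
                       seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    v <- matrix(0, n_nodes, n_nodes)
    v[upper.tri(v)] <- rnorm(sum(upper.tri(v)), sd = sd)
    v <- v + t(v)
    structure(list(values = v, group = group), class = "difference_matrix")
  })
}

# Dense symmetric connectivity matrix with community block structure plus
# noise; ground-truth membership in attr "communities".
planted_block_matrix <- function(n_nodes = 40L, n_comm = 4L, within = 0.6,
                                 between = 0.05, noise = 0.05, seed = 1L) {
  set.seed(seed)
  memb <- rep(seq_len(n_comm), length.out = n_nodes)
  v <- matrix(between, n_nodes, n_nodes)
  same <- outer(memb, memb, `==`)
  v[same] <- within
  v <- v + matrix(rnorm(n_nodes^2, sd = noise), n_nodes, n_nodes)
  v <- (v + t(v)) / 2
  v[v < 0] <- 0
  diag(v) <- 0
  cm <- connectivity_matrix(v, directed = FALSE, scale = "fisher_z")
  attr(cm, "communities") <- memb
  cm
}
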