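test_that("correlation map matches direct per-voxel Pearson", {
  ts <- toy_study()
  seeds <- suppressWarnings(place_all_seeds(ts$atlas))
  stc <- seed_timecourse(ts$series, seeds[[1]])
  cmap <- correlation_map(ts$series, stc)
  d <- dim(ts$series$data)
  m <- matrix(ts$series$data, prod(d[1:3]), d[4])
  for (v in sample(which(ts$series$brain_mask), 10))
    expect_equal(cmap[arrayInd(v, d[1:3])], cor(m[v, ], stc),
                 tolerance = 1e-12)
  # self-correlation at a 1-voxel seed is 1; negated voxel gives -1
  at1 <- box_atlas(list(list(x = 1, y = 1, z = 1),
                        list(x = 2, y = 1, z = 1)), shape = c(2, 1, 1))
  tc <- cbind(rnorm(20), 0)
  tc[, 2] <- -tc[, 1]
  b1 <- bold_from_voxel_tcs(at1, tc)
  cm1 <- correlation_map(b1, tc[, 1])
  expect_equal(cm1[1, 1, 1], 1)
  expect_equal(cm1[2, 1, 1], -1)
  expect_error(correlation_map(b1, rep(1, 20)), "constant")
})

test_that("r_to_p matches the t transform and is monotone", {
  expect_equal(r_to_p(0, 30), 1)
  expect_equal(r_to_p(0.5, 30), 0.0048999337, tolerance = 1e-7)
  expect_equal(r_to_p(1, 30), 0)
  expect_equal(r_to_p(-0.5, 30), r_to_p(0.5, 30))
  rs <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(r_to_p(rs, 20)) < 0))
  expect_error(r_to_p(0.5, 3), "n >= 4")
})

test_that("BH threshold agrees with the hand-stepped rule", {
  expect_equal(fdr_threshold(c(0.001, 0.02, 0.9), q = 0.05), 0.02)
  expect_equal(fdr_threshold(rep(1, 10), q = 0.05), 0)
  expect_equal(fdr_threshold(rep(0, 10), q = 0.05), 0)  # all pass at p = 0
  set.seed(1)
  for (rep in 1:20) {
    p <- runif(50)^2
    expect_equal(fdr_threshold(p, 0.05), bh_cutoff_oracle(p, 0.05))
  }
  expect_error(fdr_threshold(numeric(0)), "empty")
  expect_error(fdr_threshold(c(0.5, 1.2)), "0, 1")
})

test_that("MSRA matrix equals the brute-force reimplementation", {
  ts <- toy_study()
  seeds <- suppressWarnings(place_all_seeds(ts$atlas))
  got <- msra_matrix(ts$series, ts$atlas, seeds, q = 0.05)
  want <- msra_oracle(ts$series, ts$atlas, seeds, q = 0.05)
  expect_true(got$directed)
  expect_lt(max(abs(got$values - want)), 1e-10)
  expect_true(all(diag(got$values) == 0))
})

test_that("SRCC matrix equals the pairwise Pearson + BH oracle and is symmetric", {
  ts <- toy_study(seed = 7)
  seeds <- suppressWarnings(place_all_seeds(ts$atlas))
  got <- srcc_matrix(ts$series, seeds, q = 0.05)
  tcs <- sapply(seeds, function(s) seed_timecourse(ts$series, s))
  want <- pairwise_oracle(tcs, 0.05)
  expect_false(got$directed)
  expect_lt(max(abs(got$values - want)), 1e-10)
  expect_identical(got$values, t(got$values))
  # duplicated time-course across two regions -> entry 1
  at1 <- box_atlas(list(list(x = 1, y = 1, z = 1),
                        list(x = 2, y = 1, z = 1),
                        list(x = 3, y = 1, z = 1)), shape = c(3, 1, 1))
  set.seed(3)
  tc <- cbind(rnorm(30), 0, rnorm(30))
  tc[, 2] <- tc[, 1]
  b <- bold_from_voxel_tcs(at1, tc)
  sds <- suppressWarnings(place_all_seeds(at1))
  dup <- srcc_matrix(b, sds, q = 0.05)
  expect_equal(dup$values[1, 2], 1)
  expect_warning(zdup <- fisher_z(dup), "clipped")
  expect_equal(zdup$values[1, 2], atanh(1 - 1e-7))
})

test_that("RCCA matrix equals a PCA + pairwise oracle with sane diagnostics", {
  ts <- toy_study(seed = 11)
  got <- rcca_matrix(ts$series, ts$atlas, q = 0.05)
  # oracle: PC1 score series per region by explicit eigen-decomposition
  d <- dim(ts$series$data)
  m <- matrix(ts$series$data, prod(d[1:3]), d[4])
  scores <- matrix(0, d[4], n_regions(ts$atlas))
  for (i in seq_len(n_regions(ts$atlas))) {
    x <- t(m[which(ts$atlas$labels == i), , drop = FALSE])
    xc <- scale(x, center = TRUE, scale = FALSE)
    ev <- eigen(cov(xc))
    sc <- xc %*% ev$vectors[, 1]
    if (cor(sc, rowMeans(x)) < 0) sc <- -sc
    scores[, i] <- sc
    expl <- ev$values[1] / sum(ev$values)
    expect_equal(got$diagnostics$explained_variance[i], expl,
                 tolerance = 1e-10)
  }
  want <- pairwise_oracle(scores, 0.05)
  expect_lt(max(abs(got$matrix$values - want)), 1e-10)
  expect_true(all(got$diagnostics$explained_variance > 0 &
                  got$diagnostics$explained_variance <= 1))
})

test_that("RCCA degenerate cases: identical voxels and two-voxel noise regions", {
  at <- box_atlas(list(list(x = 1:3, y = 1, z = 1),
                       list(x = 1:2, y = 2, z = 1)), shape = c(3, 2, 1))
  set.seed(5)
  base <- rnorm(400)
  tc <- cbind(base, base, base, rnorm(400), rnorm(400))  # region 1: identical
  b <- bold_from_voxel_tcs(at, tc)
  got <- rcca_matrix(b, at, q = 0.05)
  expect_equal(got$diagnostics$explained_variance[1], 1, tolerance = 1e-10)
  # two independent equal-variance voxels split variance ~ 50/50
  expect_equal(got$diagnostics$explained_variance[2], 0.5, tolerance = 0.1)
})

test_that("fisher z transform: closed form, odd symmetry, zeros preserved", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061443, tolerance = 1e-9)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  m <- connectivity_matrix(matrix(c(0, 0.5, 0.5, 0), 2), directed = FALSE)
  z <- fisher_z(m)
  expect_equal(z$scale, "fisher_z")
  expect_equal(z$values[1, 2], atanh(0.5))
  expect_equal(z$values[1, 1], 0)
  expect_warning(fisher_z(1), "clipped")
})

test_that("noiseless homogeneous regions: MSRA reduces to SRCC-like saturation", {
  at <- box_atlas(list(list(x = 1:2, y = 1:2, z = 1),
                       list(x = 3:4, y = 1:2, z = 1)), shape = c(4, 2, 1))
  spec <- community_spec(c(1, 1), signal_gain = 1, noise_sd = 1e-9,
                         region_noise_sd = 1e-9)
  b <- simulate_bold(at, spec, n_volumes = 40, seed = 2)
  seeds <- suppressWarnings(place_all_seeds(at))
  m <- msra_matrix(b, at, seeds)
  expect_gt(min(m$values[row(m$values) != col(m$values)]), 0.999)
})

test_that("binarized edge count is non-increasing in the z cutoff", {
  ts <- toy_study(seed = 9, n_t = 80)
  seeds <- suppressWarnings(place_all_seeds(ts$atlas))
  z <- fisher_z(srcc_matrix(ts$series, seeds))
  counts <- sapply(seq(0, 1.5, by = 0.1), function(cut)
    sum(z$values[upper.tri(z$values)] >= cut & z$values[upper.tri(z$values)] > 0))
  expect_true(all(diff(counts) <= 0))
})

test_that("community-structured data: MSRA nonzero mode sits above the FDR threshold", {
  at <- make_toy_atlas(12, c(14, 14, 7), min_region_voxels = 6, seed = 21)
  spec <- community_spec(rep(1:3, length.out = 12), signal_gain = 1,
                         noise_sd = 1, region_noise_sd = 0.5)
  b <- simulate_bold(at, spec, n_volumes = 200, seed = 22)
  seeds <- suppressWarnings(place_all_seeds(at))
  m <- msra_matrix(b, at, seeds)
  nz <- m$values[m$values != 0]
  h <- hist(nz, breaks = 20, plot = FALSE)
  mode_r <- h$mids[which.max(h$counts)]
  expect_gt(mode_r, m$fdr_threshold_r)
})
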