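# Independent brute-force oracles: per-voxel Pearson via stats::cor on
# loops, Benjamini-Hochberg stepped by hand, means via explicit subsetting.

bh_cutoff_oracle <- function(p, q) {
  ps <- sort(p)
  ok <- 0
  for (i in seq_along(ps)) if (ps[i] <= i / length(ps) * q) ok <- i
  if (ok == 0) 0 else ps[ok]
}

msra_oracle <- function(series, atlas, seeds, q) {
  r_n <- n_regions(atlas)
  n_t <- dim(series$data)[4]
  mask_idx <- which(series$brain_mask)
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  out <- matrix(0, r_n, r_n)
  for (s in seq_len(r_n)) {
    stc <- seed_timecourse(series, seeds[[s]])
    rv <- numeric(length(mask_idx))
    for (v in seq_along(mask_idx))
      rv[v] <- suppressWarnings(cor(m[mask_idx[v], ], stc))
    rv[is.na(rv)] <- 0
    pv <- sapply(rv, function(r) {
      if (abs(r) >= 1) return(0)
      tt <- r * sqrt((n_t - 2) / (1 - r^2))
      2 * pt(-abs(tt), n_t - 2)
    })
    cut <- bh_cutoff_oracle(pv, q)
    sig <- pv <= cut & rv > 0
    labs <- atlas$labels[mask_idx]
    for (tgt in seq_len(r_n)) {
      if (tgt == s) next
      pick <- sig & labs == tgt
      if (any(pick)) out[s, tgt] <- mean(rv[pick])
    }
  }
  out
}

pairwise_oracle <- function(tcs, q) {
  r_n <- ncol(tcs)
  n_t <- nrow(tcs)
  cc <- matrix(0, r_n, r_n)
  pv <- c()
  pairs <- list()
  for (i in 1:(r_n - 1)) for (j in (i + 1):r_n) {
    r <- cor(tcs[, i], tcs[, j])
    cc[i, j] <- cc[j, i] <- r
    tt <- r * sqrt((n_t - 2) / (1 - r^2))
    pv <- c(pv, 2 * pt(-abs(tt), n_t - 2))
    pairs <- c(pairs, list(c(i, j)))
  }
  cut <- bh_cutoff_oracle(pv, q)
  for (k in seq_along(pairs)) {
    if (pv[k] > cut) {
      cc[pairs[[k]][1], pairs[[k]][2]] <- 0
      cc[pairs[[k]][2], pairs[[k]][1]] <- 0
    }
  }
  cc
}

toy_study <- function(seed = 42, n_t = 50) {
  at <- box_atlas(list(list(x = 1:2, y = 1:2, z = 1),
                       list(x = 3:4, y = 1:2, z = 1),
                       list(x = 1:2, y = 3:4, z = 1),
                       list(x = 3:4, y = 3:4, z = 1),
                       list(x = 5, y = 1:4, z = 1)),
                  shape = c(5, 4, 1))
  spec <- community_spec(c(1, 1, 2, 2, 1), signal_gain = 1, noise_sd = 1,
                         region_noise_sd = 0.5)
  b <- simulate_bold(at, spec, n_volumes = n_t, seed = seed)
  list(atlas = at, series = b)
}
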