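#' Connectivity matrix objects
#'
#' A `connectivity_matrix` wraps an R x R matrix of region-pair correlation
#' (or Fisher z) values with its metadata: directedness (TRUE for the
#' pseudo-directed MSRA matrix, FALSE for SRCC/RCCA), value scale, the FDR
#' level used for significance zeroing and the realized correlation
#' threshold. Zeros mean "not significant"; the diagonal is always 0.
#'
#' @param values R x R numeric matrix.
#' @param directed Logical.
#' @param scale `"pearson_r"` or `"fisher_z"`.
#' @param fdr_q FDR level used (NA if none).
#' @param fdr_threshold_r Realized |r| significance threshold (NA if none).
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, directed, scale = "pearson_r",
                                fdr_q = NA_real_,
                                fdr_threshold_r = NA_real_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  diag(values) <- 0
  if (!directed && !isTRUE(all.equal(values, t(values))))
    stop("undirected matrix must be symmetric", call. = FALSE)
  structure(
    list(values = values, directed = directed, scale = scale,
         fdr_q = fdr_q, fdr_threshold_r = fdr_threshold_r),
    class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  nz <- sum(x$values != 0)
  cat(sprintf(
    "%s connectivity matrix: %d regions, %d nonzero entries (%s scale)\n",
    if (x$directed) "Directed (pseudo-directed)" else "Symmetric",
    nrow(x$values), nz, x$scale))
  if (!is.na(x$fdr_q))
    cat(sprintf("  FDR q = %.3g, realized |r| threshold ~ %.4g\n",
                x$fdr_q, x$fdr_threshold_r))
  invisible(x)
}

#' @export
as.matrix.connectivity_matrix <- function(x, ...) x$values

#' Whole-brain correlation map of one seed time-course
#'
#' Pearson correlation of `seed_tc` with every in-mask voxel time-course.
#' Zero-variance voxels get r = 0 and are flagged in the `"flagged"`
#' attribute. Background voxels are NA.
#'
#' @param series A `bold_series`.
#' @param seed_tc Numeric time-course of length t.
#' @return 3D array of correlations (NA outside the mask).
#' @export
correlation_map <- function(series, seed_tc) {
  if (length(seed_tc) != n_timepoints(series))
    stop("seed time-course length must match the series", call. = FALSE)
  if (stats::sd(seed_tc) == 0)
    stop("seed time-course is constant", call. = FALSE)
  tc <- mask_matrix(series)
  r <- fast_cor_vec(tc, seed_tc)
  flagged <- which(is.na(r))
  r[flagged] <- 0
  out <- array(NA_real_, dim = dim(series$data)[1:3])
  out[which(series$brain_mask)] <- r
  attr(out, "flagged") <- flagged
  out
}

# Pearson r of each column of t x V matrix `tc` with vector y; NA for
# zero-variance columns.
fast_cor_vec <- function(tc, y) {
  yc <- y - mean(y)
  cm <- colMeans(tc)
  num <- as.vector(crossprod(tc, yc)) - nrow(tc) * cm * mean(yc)
  ss <- colSums(tc^2) - nrow(tc) * cm^2
  den <- sqrt(ss * sum(yc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  pmin(1, pmax(-1, r))
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @param n_timepoints Sample size n (>= 4).
#' @return Two-sided p-value(s); `|r| = 1` maps to 0.
#' @export
r_to_p <- function(r, n_timepoints) {
  if (n_timepoints < 4) stop("need n >= 4", call. = FALSE)
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tt <- r[ok] * sqrt((n_timepoints - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n_timepoints - 2)
  if (length(dim(r))) p <- array(p, dim = dim(r))
  p
}

# Inverse: |r| whose two-sided p equals `p` at sample size n.
p_to_r <- function(p, n_timepoints) {
  tt <- stats::qt(1 - p / 2, df = n_timepoints - 2)
  tt / sqrt(n_timepoints - 2 + tt^2)
}

#' Benjamini-Hochberg step-up p-value cutoff
#'
#' Returns the largest sorted p-value `p_(i)` with `p_(i) <= (i/m) * q`, or
#' 0 when no p-value qualifies (no discoveries).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return The p-value cutoff; values `<=` it are declared significant.
#' @export
fdr_threshold <- function(pvalues, q = 0.05) {
  pvalues <- as.vector(pvalues)
  if (length(pvalues) == 0L) stop("empty p-value set", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  ps <- sort(pvalues)
  m <- length(ps)
  ok <- which(ps <= seq_len(m) / m * q)
  if (length(ok) == 0L) 0 else ps[max(ok)]
}

#' Pseudo-directed multi-seed region analysis (MSRA) matrix
#'
#' For every seed region s: correlate its seed mean time-course with every
#' brain voxel, declare voxels significant by Benjamini-Hochberg FDR at
#' level `q` over all in-mask voxels of that map, then set entry (s, t) to
#' the mean of the significant positive correlations among voxels labelled
#' t (0 if none). Fixed seeds versus data-driven target voxels make the
#' matrix asymmetric ("pseudo-directed": rows are seed regions, columns are
#' target regions; no causal claim). The diagonal is excluded.
#'
#' @param series A preprocessed `bold_series`.
#' @param atlas A `label_atlas` on the same grid.
#' @param seeds Seed list from [place_all_seeds()]; must cover all regions.
#' @param q FDR level (default 0.05).
#' @param anti Invert correlation signs first, to study anti-correlated
#'   networks (default FALSE).
#' @return A directed `connectivity_matrix` (scale `"pearson_r"`). Its
#'   `fdr_threshold_r` is the mean over seed rows of the realized `|r|`
#'   threshold; per-row thresholds are in attribute `"row_threshold_r"` of
#'   the values matrix.
#' @export
msra_matrix <- function(series, atlas, seeds, q = 0.05, anti = FALSE) {
  r_n <- n_regions(atlas)
  if (length(seeds) < r_n) stop("seeds must cover all regions", call. = FALSE)
  n_t <- n_timepoints(series)
  mask_idx <- which(series$brain_mask)
  vlab <- atlas$labels[mask_idx]
  tc <- mask_matrix(series)
  vals <- matrix(0, r_n, r_n)
  row_thr <- rep(NA_real_, r_n)
  for (s in seq_len(r_n)) {
    stc <- seed_timecourse(series, seeds[[s]])
    if (stats::sd(stc) == 0) {
      warning("constant seed time-course in region ", s, "; row zeroed",
              call. = FALSE)
      next
    }
    rv <- fast_cor_vec(tc, stc)
    rv[is.na(rv)] <- 0
    if (anti) rv <- -rv
    pv <- r_to_p(rv, n_t)
    cut <- fdr_threshold(pv, q)
    sig <- pv <= cut & rv > 0
    row_thr[s] <- p_to_r(cut, n_t)
    if (!any(sig)) next
    means <- tapply(rv[sig], vlab[sig], mean)
    tgt <- as.integer(names(means))
    vals[s, tgt] <- means
  }
  diag(vals) <- 0
  attr(vals, "row_threshold_r") <- row_thr
  connectivity_matrix(vals, directed = TRUE, scale = "pearson_r", fdr_q = q,
                      fdr_threshold_r = mean(row_thr, na.rm = TRUE))
}

#' Seed-region cross-correlation (SRCC) matrix
#'
#' Pairwise Pearson correlation of the seed mean time-courses of all
#' regions, with Benjamini-Hochberg FDR applied across the R(R-1)/2 unique
#' off-diagonal p-values; non-significant entries are set to 0.
#'
#' @inheritParams msra_matrix
#' @return A symmetric `connectivity_matrix` (scale `"pearson_r"`).
#' @export
srcc_matrix <- function(series, seeds, q = 0.05, anti = FALSE) {
  tcs <- vapply(seeds, function(s) seed_timecourse(series, s),
                numeric(n_timepoints(series)))
  cross_correlation_matrix(tcs, q = q, anti = anti)
}

#' Regional cross-correlation (RCCA) matrix on first principal components
#'
#' Summarizes each region's voxel time-courses by the score series of their
#' first principal component (time points as observations, voxels as
#' variables), sign-fixed to correlate non-negatively with the region mean,
#' then proceeds as SRCC (pairwise Pearson + matrix-level FDR). Using PC1
#' instead of the plain mean reduces the bias of averaging many voxels in
#' large, inhomogeneous regions. One-voxel regions use the voxel itself.
#'
#' @inheritParams msra_matrix
#' @return List with `matrix` (symmetric `connectivity_matrix`) and
#'   `diagnostics` (data.frame: region, explained variance fraction of PC1).
#' @export
rcca_matrix <- function(series, atlas, q = 0.05, anti = FALSE) {
  r_n <- n_regions(atlas)
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  scores <- matrix(NA_real_, d[4], r_n)
  expl <- rep(NA_real_, r_n)
  for (i in seq_len(r_n)) {
    idx <- which(atlas$labels == i)
    x <- t(m[idx, , drop = FALSE])          # t x n_vox
    mu <- rowMeans(x)
    if (all(apply(x, 2, stats::sd) == 0)) {
      warning("region ", i, " has zero variance; row zeroed", call. = FALSE)
      scores[, i] <- 0
      expl[i] <- NA_real_
      next
    }
    if (ncol(x) == 1L) {
      scores[, i] <- x[, 1]
      expl[i] <- 1
    } else {
      pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
      sc <- pc$x[, 1]
      if (stats::sd(mu) > 0 && stats::cor(sc, mu) < 0) sc <- -sc
      scores[, i] <- sc
      expl[i] <- pc$sdev[1]^2 / sum(pc$sdev^2)
    }
  }
  cm <- cross_correlation_matrix(scores, q = q, anti = anti)
  list(matrix = cm,
       diagnostics = data.frame(region = seq_len(r_n),
                                explained_variance = expl))
}

# Shared SRCC/RCCA core: pairwise Pearson of the columns of `tcs`, BH FDR
# over the unique off-diagonal p-values, zero non-significant entries.
cross_correlation_matrix <- function(tcs, q = 0.05, anti = FALSE) {
  sds <- apply(tcs, 2, stats::sd)
  cc <- matrix(0, ncol(tcs), ncol(tcs))
  ok <- sds > 0
  if (any(!ok))
    warning("constant time-course(s): ", paste(which(!ok), collapse = ", "),
            "; rows zeroed", call. = FALSE)
  if (sum(ok) >= 2)
    cc[ok, ok] <- stats::cor(tcs[, ok, drop = FALSE])
  if (anti) cc <- -cc
  diag(cc) <- 0
  n_t <- nrow(tcs)
  ut <- upper.tri(cc)
  pv <- r_to_p(cc[ut], n_t)
  cut <- fdr_threshold(pv, q)
  keep <- matrix(FALSE, nrow(cc), ncol(cc))
  keep[ut] <- pv <= cut
  keep <- keep | t(keep)
  cc[!keep] <- 0
  connectivity_matrix(cc, directed = FALSE, scale = "pearson_r", fdr_q = q,
                      fdr_threshold_r = p_to_r(cut, n_t))
}

#' Fisher z transform
#'
#' Elementwise `atanh`; zeros stay zero, so "not significant" survives the
#' transform. Values with `|r| >= 1` are clipped to `1 - 1e-7` in magnitude
#' with a warning.
#'
#' @param x Numeric vector/matrix or `connectivity_matrix` in r scale.
#' @return Same shape; for a `connectivity_matrix`, scale becomes
#'   `"fisher_z"`.
#' @export
fisher_z <- function(x) {
  if (inherits(x, "connectivity_matrix")) {
    if (x$scale == "fisher_z") return(x)
    x$values <- fisher_z(x$values)
    x$scale <- "fisher_z"
    return(x)
  }
  if (any(abs(x) >= 1)) {
    warning("values with |r| >= 1 clipped before atanh", call. = FALSE)
    x <- pmin(pmax(x, -(1 - 1e-7)), 1 - 1e-7)  # arg order keeps dims
  }
  atanh(x)
}
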