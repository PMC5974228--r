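#' Overall correlation between two connectivity matrices
#'
#' Pearson r over corresponding off-diagonal entries: the full off-diagonal
#' if either matrix is directed, the upper triangle if both are symmetric.
#'
#' @param mat_a,mat_b `connectivity_matrix` objects or plain square
#'   matrices of equal size and node order.
#' @param directed Directedness override for plain matrices; inferred from
#'   `connectivity_matrix` inputs.
#' @return Pearson r (NA with a warning if either vector has no variance).
#' @export
overall_r <- function(mat_a, mat_b, directed = NULL) {
  dir_a <- if (inherits(mat_a, "connectivity_matrix")) mat_a$directed else directed
  dir_b <- if (inherits(mat_b, "connectivity_matrix")) mat_b$directed else directed
  a <- if (inherits(mat_a, "connectivity_matrix")) mat_a$values else as.matrix(mat_a)
  b <- if (inherits(mat_b, "connectivity_matrix")) mat_b$values else as.matrix(mat_b)
  if (!identical(dim(a), dim(b)))
    stop("matrices must have identical shape", call. = FALSE)
  use_full <- isTRUE(dir_a) || isTRUE(dir_b) || is.null(dir_a) || is.null(dir_b)
  sel <- if (use_full) row(a) != col(a) else upper.tri(a)
  va <- a[sel]; vb <- b[sel]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero variance in off-diagonal entries; overall r undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Jaccard index of two region sets
#'
#' `|A  intersect B| / |A union B|`; defined as 0 (with a warning) when both
#' sets are empty.
#'
#' @param set_a,set_b Vectors of region ids (duplicates ignored).
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0L) {
    warning("both sets empty; Jaccard defined as 0", call. = FALSE)
    return(0)
  }
  length(intersect(set_a, set_b)) / u
}

#' Region sets of binarized component maps
#'
#' A region belongs to a component if its mean component z-score exceeds
#' `z_cut`.
#'
#' @param zmaps 4D array (x, y, z, component) of z-score maps on the atlas
#'   grid.
#' @param atlas A `label_atlas`.
#' @param z_cut Binarization threshold (default 0.3).
#' @return List (one per component) of integer region-id vectors.
#' @export
binarize_components <- function(zmaps, atlas, z_cut = 0.3) {
  zb <- region_component_means(zmaps, atlas)
  lapply(seq_len(nrow(zb)), function(cc) unname(which(zb[cc, ] > z_cut)))
}

# Component x region matrix of region-mean z-scores.
region_component_means <- function(zmaps, atlas) {
  d <- dim(zmaps)
  if (!identical(d[1:3], dim(atlas$labels)))
    stop("component maps must share the atlas grid", call. = FALSE)
  idx <- which(atlas$labels > 0L)
  vlab <- atlas$labels[idx]
  m <- matrix(zmaps, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  t(rowsum(m, vlab) / as.vector(table(vlab)))
}

#' ICA co-activation index matrix
#'
#' With `zbar(c, i)` the mean z-score of component c over region i, clipped
#' at 0, the index is `values(i, j) = sum_c (zbar(c,i) * zbar(c,j))^k`
#' (`formula = "per_component"`, the default) or
#' `(sum_c zbar(c,i) * zbar(c,j))^k` (`formula = "pooled"`). The power
#' factor emphasizes intense (k > 1) or weak (k < 1) co-activation.
#'
#' @param zmaps 4D component z-score maps.
#' @param atlas A `label_atlas`.
#' @param power_k Positive exponent k.
#' @param formula Where the power applies (see above).
#' @return A `coactivation_matrix`: list with `values` (symmetric,
#'   nonnegative, zero diagonal) and `power_k`.
#' @export
coactivation_index <- function(zmaps, atlas, power_k = 1,
                               formula = c("per_component", "pooled")) {
  formula <- match.arg(formula)
  if (power_k <= 0) stop("'power_k' must be > 0", call. = FALSE)
  zb <- pmax(region_component_means(zmaps, atlas), 0)
  vals <- if (formula == "per_component") {
    r_n <- ncol(zb)
    out <- matrix(0, r_n, r_n)
    for (cc in seq_len(nrow(zb)))
      out <- out + outer(zb[cc, ], zb[cc, ])^power_k
    out
  } else crossprod(zb)^power_k
  diag(vals) <- 0
  structure(list(values = vals, power_k = power_k, formula = formula),
            class = "coactivation_matrix")
}

#' Method-vs-ICA similarity as a function of the power factor
#'
#' Computes `overall_r(coactivation_index(., k), method matrix)` for every
#' method and every k on a grid.
#'
#' @param zmaps 4D component z-score maps.
#' @param atlas A `label_atlas`.
#' @param matrices Named list of `connectivity_matrix` objects (one per
#'   method), shared node order with the atlas.
#' @param k_grid Power factors (default `c(0.5, 1, 2)`).
#' @return Data.frame (method, power_k, overall_r).
#' @export
similarity_vs_power <- function(zmaps, atlas, matrices,
                                k_grid = c(0.5, 1, 2)) {
  rows <- expand.grid(method = names(matrices), power_k = k_grid,
                      stringsAsFactors = FALSE)
  rows$overall_r <- mapply(function(meth, k) {
    ca <- coactivation_index(zmaps, atlas, power_k = k)
    overall_r(matrices[[meth]],
              connectivity_matrix(ca$values, directed = FALSE,
                                  scale = "pearson_r"))
  }, rows$method, rows$power_k)
  rows
}

#' Reproducibility variance report across subjects
#'
#' Per-connection sample variance of Fisher-z values across subjects,
#' normalized by the maximum variance so all entries lie in `[0, 1]`;
#' the median over connections summarizes reproducibility (lower = more
#' reproducible), with a 95% bootstrap confidence interval from resampling
#' connections. The mean-subtracted matrix shows where variance concentrates.
#'
#' @param per_subject_matrices List (length >= 3) of `connectivity_matrix`
#'   objects or plain matrices, one per subject, common node order.
#' @param n_boot Bootstrap resamples for the median CI (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return A `variance_report`: list with `variance_matrix`, `median`,
#'   `median_ci`, `mean_subtracted_matrix`, `connection_variances`.
#' @export
variance_report <- function(per_subject_matrices, n_boot = 1000L, seed = 1L) {
  if (length(per_subject_matrices) < 3L)
    stop("need at least 3 subjects", call. = FALSE)
  directed <- any(vapply(per_subject_matrices, function(m)
    if (inherits(m, "connectivity_matrix")) m$directed else TRUE, logical(1)))
  mats <- lapply(per_subject_matrices, function(m)
    if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m))
  arr <- simplify2array(mats)
  vm <- apply(arr, c(1, 2), stats::var)
  vmax <- max(vm)
  if (vmax > 0) vm <- vm / vmax
  sel <- if (directed) row(vm) != col(vm) else upper.tri(vm)
  cv <- vm[sel]
  med <- stats::median(cv)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    stats::median(sample(cv, replace = TRUE)), numeric(1)))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  structure(
    list(variance_matrix = vm, median = med, median_ci = ci,
         mean_subtracted_matrix = vm - mean(cv), connection_variances = cv),
    class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf(
    "Variance report: median normalized variance %.4g [%.4g, %.4g] (95%% CI)\n",
    x$median, x$median_ci[1], x$median_ci[2]))
  invisible(x)
}

#' Kruskal-Wallis test across methods' connection variances
#'
#' Rank-based comparison of the connection-variance distributions of two or
#' more analysis methods (e.g., their `variance_report`s).
#'
#' @param reports Named list of `variance_report` objects (or numeric
#'   vectors of connection variances), length >= 2.
#' @return `htest` object from [stats::kruskal.test()].
#' @export
kruskal_wallis_medians <- function(reports) {
  if (length(reports) < 2L) stop("need >= 2 methods", call. = FALSE)
  samples <- lapply(reports, function(r)
    if (inherits(r, "variance_report")) r$connection_variances else
      as.numeric(r))
  if (length(unique(unlist(samples))) == 1L)
    warning("all values identical across methods; test degenerate",
            call. = FALSE)
  stats::kruskal.test(samples)
}
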