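#' Per-subject session difference matrices
#'
#' Elementwise post - pre Fisher-z difference per subject. Inputs are the
#' per-subject, per-session connectivity matrices in Fisher-z scale with a
#' common node order.
#'
#' @param pre,post Lists (same length, same subject order) of
#'   `connectivity_matrix` objects or plain matrices.
#' @param group Character vector of group labels, one per subject.
#' @return List of `difference_matrix` objects: `values` (R x R), `group`.
#' @export
difference_matrices <- function(pre, post, group) {
  if (length(pre) != length(post) || length(pre) != length(group))
    stop("pre, post and group must have one entry per subject", call. = FALSE)
  lapply(seq_along(pre), function(k) {
    a <- if (inherits(pre[[k]], "connectivity_matrix")) pre[[k]]$values else
      as.matrix(pre[[k]])
    b <- if (inherits(post[[k]], "connectivity_matrix")) post[[k]]$values else
      as.matrix(post[[k]])
    if (!identical(dim(a), dim(b)))
      stop("pre/post shape mismatch for subject ", k, call. = FALSE)
    structure(list(values = b - a, group = group[k]),
              class = "difference_matrix")
  })
}

#' Connection universe helpers
#'
#' `all_connections` enumerates every off-diagonal cell (directed) or unique
#' pair (undirected) of an R-node matrix. `connection_universe` forms the
#' union of the edges of several graphs (e.g., the four group-average
#' session graphs thresholded at an average degree), the default analyzed
#' set for the paired network-based statistic.
#'
#' @param n_nodes Number of regions.
#' @param directed Directed connection set?
#' @return Integer matrix with columns i, j, one row per connection.
#' @export
all_connections <- function(n_nodes, directed = FALSE) {
  idx <- if (directed) {
    w <- which(matrix(TRUE, n_nodes, n_nodes) & diag(n_nodes) == 0,
               arr.ind = TRUE)
    w
  } else {
    which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  }
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' @param graphs List of `network_graph` objects.
#' @rdname all_connections
#' @export
connection_universe <- function(graphs) {
  ed <- unique(do.call(rbind, lapply(graphs, function(g) {
    e <- as.matrix(g$edges[, c("from", "to")])
    if (!g$directed) e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e
  })))
  colnames(ed) <- c("i", "j")
  ed[order(ed[, 1], ed[, 2]), , drop = FALSE]
}

# Subjects x connections matrix of difference values over `connections`.
diff_values <- function(diffs, connections) {
  t(vapply(diffs, function(d)
    d$values[cbind(connections[, 1], connections[, 2])],
    numeric(nrow(connections))))
}

#' Paired t-statistics per connection
#'
#' One-sample t of the subjects' session differences against 0 on every
#' analyzed connection, with two-sided p-values. Connections whose
#' differences have zero variance across subjects get p = 1 and are flagged.
#'
#' @param diffs List of `difference_matrix` (>= 3 subjects).
#' @param connections Connection matrix (columns i, j) from
#'   [all_connections()] or [connection_universe()].
#' @return List with `t`, `p` (vectors along `connections`), `flagged`
#'   (indices of degenerate connections), and `connections`.
#' @export
paired_t_pvalues <- function(diffs, connections) {
  if (length(diffs) < 3L) stop("need >= 3 subjects", call. = FALSE)
  x <- diff_values(diffs, connections)
  paired_t_core(x, connections)
}

paired_t_core <- function(x, connections) {
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * mu^2) / (n - 1))
  s[s < 0 | is.na(s)] <- 0
  tt <- ifelse(s > 0, mu / (s / sqrt(n)), 0)
  p <- ifelse(s > 0, 2 * stats::pt(-abs(tt), df = n - 1), 1)
  list(t = tt, p = p, flagged = which(s == 0), connections = connections)
}

#' First-level threshold from the control group's p-values
#'
#' The cutoff at or below which exactly `floor(fraction * m)` control
#' connections fall — the set of supra-threshold links corresponding to
#' `fraction` hypothetical false-positive connections, under the hypothesis
#' that the control session has no systematic pre/post modulation.
#'
#' @param control_p Control-group p-values over the analyzed connections.
#' @param fraction Supra-threshold fraction (default 0.01).
#' @return The p-value cutoff.
#' @export
first_level_threshold <- function(control_p, fraction = 0.01) {
  m <- length(control_p)
  k <- floor(fraction * m)
  if (k < 1L)
    stop(sprintf("fraction %.3g of %d connections is below one connection",
                 fraction, m), call. = FALSE)
  sort(control_p)[k]
}

#' Supra-threshold component extraction with control-size elimination
#'
#' Builds the supra-threshold graph (connections with p <= cutoff) for both
#' groups, measures connected components in edges on the weak (undirected)
#' skeleton, and deletes every experimental component whose edge count is
#' less than or equal to the largest control component. Unlike the
#' traditional network-based statistic, the surviving set may comprise more
#' than one component.
#'
#' @param exp_p Experimental-group p-values along `connections`.
#' @param cutoff First-level p cutoff.
#' @param control_p Control-group p-values along `connections`.
#' @param connections Connection matrix (columns i, j).
#' @param exp_t Optional experimental t-statistics to attach to surviving
#'   edges.
#' @return List with `surviving_edges` (data.frame i, j, t), `k` (edge
#'   count), `control_max_component`.
#' @export
supra_components <- function(exp_p, cutoff, control_p, connections,
                             exp_t = NULL) {
  if (nrow(connections) == 0L) stop("empty connection set", call. = FALSE)
  control_max <- max_component_edges(connections[control_p <= cutoff, ,
                                                 drop = FALSE])
  sel <- which(exp_p <= cutoff)
  edges <- connections[sel, , drop = FALSE]
  keep <- component_filter(edges, control_max)
  surviving <- edges[keep, , drop = FALSE]
  sv <- data.frame(i = surviving[, 1], j = surviving[, 2])
  sv$t <- if (is.null(exp_t)) rep(NA_real_, nrow(sv)) else exp_t[sel][keep]
  list(surviving_edges = sv, k = nrow(sv), control_max_component = control_max)
}

# Edge count of the largest weakly connected component of an edge list.
max_component_edges <- function(edges) {
  if (nrow(edges) == 0L) return(0L)
  comp <- edge_components(edges)
  max(tabulate(comp))
}

# Indices of edges whose component has edge count > control_max.
component_filter <- function(edges, control_max) {
  if (nrow(edges) == 0L) return(integer(0))
  comp <- edge_components(edges)
  sizes <- tabulate(comp)
  which(sizes[comp] > control_max)
}

# Component id per edge (weak skeleton), via igraph.
edge_components <- function(edges) {
  verts <- unique(as.vector(edges[, 1:2]))
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(edges[, 1:2]), verts), ncol = 2), directed = FALSE)
  memb <- igraph::components(g)$membership
  memb[match(edges[, 1], verts)]
}

#' Paired network-based statistic with permutation FWE control
#'
#' Full pipeline: (1) paired t-statistics per connection in both groups;
#' (2) first-level p cutoff from the control group's `fraction` quantile
#' rule; (3) supra-threshold component extraction in the experimental group
#' with elimination of components no larger than the biggest control
#' component, yielding the observed statistic k (surviving edge count).
#' The family-wise-error-corrected p-value comes from M permutations in
#' which the subjects' difference matrices are reassigned to pseudo-groups
#' of the original sizes and steps 1-3 are recalculated in full (the
#' threshold is re-derived inside every permutation); `p_fwe = #(k' > k) / M`
#' (`tie = "gt"`, the default) or `#(k' >= k) / M` for the conservative
#' variant. When the number of distinct labelings is at most M, all of them
#' are enumerated exhaustively instead of sampled.
#'
#' @param control_diffs,exp_diffs Lists of `difference_matrix` per group
#'   (>= 3 subjects each).
#' @param connections Connection matrix (columns i, j); e.g.
#'   [all_connections()] or [connection_universe()].
#' @param fraction First-level supra-threshold fraction (default 0.01).
#' @param M Number of permutations (default 5000; < 100 warns).
#' @param seed Integer seed (mandatory: permutation sampling must be
#'   reproducible).
#' @param tie `"gt"` (strict, as in the original formulation) or `"ge"`.
#' @return A `pnbs` object: `threshold_p`, `surviving_edges`, `k`,
#'   `control_max_component`, `null_sizes`, `p_fwe`, `n_permutations`,
#'   `exhaustive`, `seed`.
#' @export
pnbs_test <- function(control_diffs, exp_diffs, connections,
                      fraction = 0.01, M = 5000L, seed, tie = c("gt", "ge")) {
  tie <- match.arg(tie)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (length(control_diffs) < 3L || length(exp_diffs) < 3L)
    stop("need >= 3 subjects per group", call. = FALSE)
  if (M < 100L) warning("M < 100 permutations gives a coarse p-value",
                        call. = FALSE)
  n_c <- length(control_diffs)
  n_e <- length(exp_diffs)
  x_all <- diff_values(c(control_diffs, exp_diffs), connections)

  run_steps <- function(ctrl_idx) {
    exp_idx <- setdiff(seq_len(n_c + n_e), ctrl_idx)
    ct <- paired_t_core(x_all[ctrl_idx, , drop = FALSE], connections)
    et <- paired_t_core(x_all[exp_idx, , drop = FALSE], connections)
    cutoff <- first_level_threshold(ct$p, fraction)
    res <- supra_components(et$p, cutoff, ct$p, connections, exp_t = et$t)
    res$cutoff <- cutoff
    res
  }

  observed <- run_steps(seq_len(n_c))
  n_lab <- choose(n_c + n_e, n_c)
  exhaustive <- n_lab <= M
  labelings <- if (exhaustive) {
    asplit(utils::combn(n_c + n_e, n_c), 2)
  } else {
    with_seed(seed, replicate(M, sample.int(n_c + n_e, n_c),
                              simplify = FALSE))
  }
  null_sizes <- vapply(labelings, function(ix) run_steps(ix)$k, numeric(1))
  m_eff <- length(null_sizes)
  p_fwe <- if (tie == "gt") sum(null_sizes > observed$k) / m_eff else
    sum(null_sizes >= observed$k) / m_eff
  structure(
    list(threshold_p = observed$cutoff,
         surviving_edges = observed$surviving_edges, k = observed$k,
         control_max_component = observed$control_max_component,
         null_sizes = null_sizes, p_fwe = p_fwe, n_permutations = m_eff,
         exhaustive = exhaustive, fraction = fraction, tie = tie,
         seed = seed),
    class = "pnbs")
}

#' @export
print.pnbs <- function(x, ...) {
  cat("Paired network-based statistic\n")
  cat(sprintf("  first-level threshold p = %.4g (fraction %.3g)\n",
              x$threshold_p, x$fraction))
  cat(sprintf("  surviving edges k = %d (largest control component: %d)\n",
              x$k, x$control_max_component))
  cat(sprintf("  p_FWE = %.4g  (%d %s permutations)\n", x$p_fwe,
              x$n_permutations,
              if (x$exhaustive) "exhaustive" else "random"))
  invisible(x)
}

#' @export
summary.pnbs <- function(object, ...) {
  print(object)
  if (object$k > 0) {
    cat("  surviving connections:\n")
    print(object$surviving_edges, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.pnbs <- function(x, ...) {
  graphics::hist(x$null_sizes, breaks = 30,
                 main = "Permutation null of surviving component size",
                 xlab = "k' (edges)", ...)
  graphics::abline(v = x$k, col = 2, lwd = 2)
  invisible(x)
}
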