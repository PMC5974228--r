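#' Threshold a connectivity matrix into a network graph
#'
#' Converts positive matrix entries into a weighted graph under one of three
#' rules: `"avg_degree"` keeps the `N * value / 2` strongest entries
#' (each edge contributes to the degree of both endpoints, so an average
#' degree d on N nodes means N*d/2 edges, directed or not), `"top_n_edges"`
#' keeps exactly `value` edges, and `"z_cutoff"` keeps entries with weight
#' `>= value`. Ties at the cut are broken by weight (descending), then source
#' id, then target id, so the edge count is exact and deterministic. If fewer
#' positive entries exist than requested, all are kept with a warning.
#'
#' @param cm A `connectivity_matrix` (any scale; weights used as-is).
#' @param rule `"avg_degree"`, `"top_n_edges"` or `"z_cutoff"`.
#' @param value Rule parameter: average degree, edge count, or weight cutoff.
#' @return A `network_graph`: list with `nodes`, `edges` (data.frame from,
#'   to, weight), `directed`, `threshold_rule`, `threshold_value`.
#' @export
threshold_graph <- function(cm, rule = c("avg_degree", "top_n_edges",
                                         "z_cutoff"), value) {
  rule <- match.arg(rule)
  v <- cm$values
  n <- nrow(v)
  if (cm$directed) {
    cand <- which(v > 0 & row(v) != col(v), arr.ind = TRUE)
  } else {
    cand <- which(v > 0 & upper.tri(v), arr.ind = TRUE)
  }
  w <- v[cand]
  ord <- order(-w, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  w <- w[ord]
  m <- switch(rule,
    avg_degree = round(n * value / 2),
    top_n_edges = value,
    z_cutoff = sum(w >= value))
  if (rule != "z_cutoff" && m > length(w)) {
    warning(sprintf("requested %d edges but only %d positive entries; %s",
                    m, length(w), "keeping all"), call. = FALSE)
    m <- length(w)
  }
  keep <- seq_len(m)
  structure(
    list(nodes = seq_len(n),
         edges = data.frame(from = cand[keep, 1], to = cand[keep, 2],
                            weight = w[keep]),
         directed = cm$directed, threshold_rule = rule,
         threshold_value = value),
    class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("Network graph: %d nodes, %d %s edges (%s rule, value %.4g)\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected",
              x$threshold_rule, x$threshold_value))
  invisible(x)
}

#' Convert a network graph to igraph
#'
#' Directed graphs can be symmetrized by summing reciprocal edge weights
#' (needed for undirected community detection).
#'
#' @param graph A `network_graph`.
#' @param symmetrize Collapse a directed graph to undirected, summing
#'   reciprocal weights (default FALSE).
#' @return An `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(graph, symmetrize = FALSE) {
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = graph$directed,
    vertices = data.frame(name = graph$nodes))
  if (graph$directed && symmetrize)
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "sum"))
  g
}

#' Modularity-based community detection at a target community count
#'
#' Louvain-style modularity optimization on the weighted graph (directed
#' graphs are symmetrized first by summing reciprocal weights). When the
#' natural partition count differs from `target_count`, a bisection search
#' over the resolution parameter finds a resolution whose partition has the
#' target count, falling back to the closest achievable count with a
#' warning. Reported modularity is always the standard (resolution 1) Q of
#' the returned partition.
#'
#' @param graph A `network_graph` with at least one edge.
#' @param target_count Desired number of communities (NULL = natural count).
#' @param seed Integer seed (Louvain output is node-order dependent).
#' @param max_iter Bisection iterations (default 40).
#' @return A `community_partition`: list with `assignment` (node ->
#'   community id, contiguous from 1), `modularity`, `n_communities`,
#'   `resolution`.
#' @export
detect_communities <- function(graph, target_count = NULL, seed = 1L,
                               max_iter = 40L) {
  if (nrow(graph$edges) == 0L) stop("graph has no edges", call. = FALSE)
  g <- as_igraph(graph, symmetrize = TRUE)
  run <- function(res) with_seed(seed, {
    cl <- igraph::cluster_louvain(g, resolution = res)
    memb <- igraph::membership(cl)
    list(memb = memb, k = length(unique(memb)))
  })
  best <- run(1)
  resolution <- 1
  if (!is.null(target_count) && best$k != target_count) {
    n_comp <- igraph::count_components(g)
    lo <- 1e-4; hi <- 1
    if (best$k < target_count) {       # need finer partition: raise resolution
      lo <- 1
      hi <- 2
      while (run(hi)$k < target_count && hi < 1e4) hi <- hi * 2
    } else {
      while (run(lo)$k > target_count && lo > 1e-8) lo <- lo / 2
    }
    closest <- best; closest_res <- 1
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      cur <- run(mid)
      if (abs(cur$k - target_count) < abs(closest$k - target_count)) {
        closest <- cur; closest_res <- mid
      }
      if (cur$k == target_count) break
      if (cur$k < target_count) lo <- mid else hi <- mid
    }
    best <- closest
    resolution <- closest_res
    if (best$k != target_count)
      warning(sprintf(
        "target of %d communities not achievable (got %d; graph has %d %s)",
        target_count, best$k, n_comp, "components"), call. = FALSE)
  }
  memb <- as.integer(factor(best$memb, levels = unique(best$memb)))
  names(memb) <- graph$nodes
  q <- igraph::modularity(g, best$memb,
                          weights = igraph::E(g)$weight)
  structure(
    list(assignment = memb, modularity = q,
         n_communities = length(unique(memb)), resolution = resolution),
    class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Partition: %d communities, Q = %.4f (resolution %.4g)\n",
              x$n_communities, x$modularity, x$resolution))
  invisible(x)
}

#' Community size table
#' @param partition A `community_partition`.
#' @return Data.frame (community, n_nodes), sizes descending.
#' @export
community_sizes <- function(partition) {
  tab <- sort(table(partition$assignment), decreasing = TRUE)
  data.frame(community = as.integer(names(tab)), n_nodes = as.integer(tab))
}

#' Drop communities below a minimum size
#'
#' @param partition A `community_partition`.
#' @param min_nodes Minimum nodes a community must have to be kept
#'   (default 4).
#' @return A `community_partition` restricted to the retained communities
#'   (nodes of dropped communities are removed from the assignment).
#' @export
filter_small <- function(partition, min_nodes = 4L) {
  tab <- table(partition$assignment)
  keep_ids <- as.integer(names(tab)[tab >= min_nodes])
  memb <- partition$assignment[partition$assignment %in% keep_ids]
  partition$assignment <- memb
  partition$n_communities <- length(keep_ids)
  partition
}

#' Deterministic 2D graph layout for plotting
#'
#' Kamada-Kawai force-based coordinates computed per connected component
#' (seeded, so repeated calls agree).
#'
#' @param graph A `network_graph`.
#' @param partition Optional `community_partition` to attach community ids.
#' @param seed Integer seed.
#' @return Data.frame (node, x, y, community).
#' @export
export_layout <- function(graph, partition = NULL, seed = 1L) {
  if (nrow(graph$edges) == 0L)
    return(data.frame(node = integer(0), x = numeric(0), y = numeric(0),
                      community = integer(0)))
  g <- as_igraph(graph, symmetrize = TRUE)
  xy <- with_seed(seed, igraph::layout_with_kk(g))
  out <- data.frame(node = graph$nodes, x = xy[, 1], y = xy[, 2])
  out$community <- if (is.null(partition)) NA_integer_ else
    unname(partition$assignment[as.character(out$node)])
  out
}

#' Is the thresholded graph fully connected?
#' @param graph A `network_graph`.
#' @return TRUE if every node is in one (weakly) connected component.
#' @export
is_fully_connected <- function(graph) {
  g <- as_igraph(graph, symmetrize = graph$directed)
  igraph::count_components(g, mode = "weak") == 1L
}
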