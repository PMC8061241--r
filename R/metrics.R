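#' Node strength
#'
#' Sum of absolute edge weights incident to each node.
#'
#' @param net a `cluster_network` or a symmetric weight matrix with zero
#'   diagonal.
#' @return named length-p numeric vector.
#' @export
node_strength <- function(net) {
  w <- .net_weights(net)
  rowSums(abs(w))
}

.net_weights <- function(net, tol = 1e-10) {
  w <- if (inherits(net, "cluster_network")) net$pcor else as.matrix(net)
  stopifnot(nrow(w) == ncol(w))
  w[abs(w) <= tol] <- 0
  w
}

# weighted graph with edge length 1/|weight|; absent edges = no direct link
.net_graph <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(abs(w) > 0, mode = "undirected",
                                           diag = FALSE)
  ends <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$dist <- 1 / abs(w[ends])
  g
}

#' Shortest-path centralities: closeness and betweenness
#'
#' Path metrics on the weighted network with edge distance `1 / |weight|`
#' (stronger associations are shorter links; sign is ignored). Closeness of a
#' node is the reciprocal of its mean shortest-path distance to the nodes it
#' can reach (0 for an isolated node), so larger values mean more central.
#' Betweenness counts, for each pair of other nodes, the fraction of shortest
#' paths between them passing through the node (fractional counting under
#' ties); unreachable pairs contribute nothing.
#'
#' @inheritParams node_strength
#' @return list with numeric vectors `closeness` and `betweenness`, each of
#'   length p, named by node.
#' @export
shortest_path_metrics <- function(net) {
  w <- .net_weights(net)
  p <- nrow(w)
  nm <- rownames(w) %||% paste0("item_", seq_len(p))
  if (p < 2 || all(w == 0)) {
    z <- stats::setNames(numeric(p), nm)
    return(list(closeness = z, betweenness = z))
  }
  g <- .net_graph(w)
  D <- igraph::distances(g, weights = igraph::E(g)$dist)
  closeness <- apply(D, 1, function(row) {
    r <- row[is.finite(row) & row > 0]
    if (!length(r)) 0 else 1 / mean(r)
  })
  betweenness <- igraph::betweenness(g, weights = igraph::E(g)$dist,
                                     directed = FALSE)
  list(closeness = stats::setNames(as.numeric(closeness), nm),
       betweenness = stats::setNames(as.numeric(betweenness), nm))
}

#' Centrality table for one or more cluster networks
#'
#' @param nets a `cluster_network` or a list of them.
#' @return data.frame with columns `cluster`, `node`, `strength`,
#'   `closeness`, `betweenness` (one row per node per cluster).
#' @export
centrality_table <- function(nets) {
  if (inherits(nets, "cluster_network")) nets <- list(nets)
  out <- lapply(nets, function(net) {
    s <- node_strength(net)
    sp <- shortest_path_metrics(net)
    data.frame(cluster = net$cluster_id, node = net$item_labels,
               strength = unname(s),
               closeness = unname(sp$closeness),
               betweenness = unname(sp$betweenness))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Global density and connectivity of a network
#'
#' Two complementary summaries over all `p(p-1)/2` node pairs: `density` is
#' the mean absolute edge weight (zero pairs included in the denominator) and
#' `connectivity` the fraction of pairs with a realised (nonzero, tolerance
#' 1e-10) edge. The two need not agree: a network can have few but strong
#' edges, or many weak ones.
#'
#' @inheritParams node_strength
#' @return list with `density`, `connectivity`, `n_edges`, `n_pairs`.
#' @export
global_connectivity <- function(net) {
  w <- .net_weights(net)
  up <- w[upper.tri(w)]
  n_pairs <- length(up)
  list(density = mean(abs(up)),
       connectivity = sum(up != 0) / n_pairs,
       n_edges = sum(up != 0), n_pairs = n_pairs)
}

#' Pairwise Kolmogorov-Smirnov comparison of centrality distributions
#'
#' For every unordered pair of clusters, the two-sample KS statistic and
#' p-value comparing the clusters' node-centrality distributions for the
#' requested measure. The p-value is exact when the sample sizes permit and
#' the data are tie-free (the usual case for p-node centrality vectors), and
#' asymptotic otherwise; the purely asymptotic approximation is badly
#' conservative at the ~10 values per network such comparisons involve. No
#' multiplicity correction is applied; the number of tests performed is
#' recorded so readers can judge for themselves.
#'
#' @param tables a centrality table as returned by [centrality_table()]
#'   covering at least two clusters.
#' @param measure `"strength"`, `"closeness"` or `"betweenness"`.
#' @return data.frame with columns `cluster_a`, `cluster_b`, `measure`, `D`,
#'   `p_value`, and attribute `n_tests`.
#' @export
ks_compare <- function(tables, measure = c("strength", "closeness", "betweenness")) {
  measure <- match.arg(measure)
  clusters <- sort(unique(tables$cluster))
  if (length(clusters) < 2) stop("need at least two clusters to compare")
  pairs <- utils::combn(clusters, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- tables[tables$cluster == pr[1], measure]
    b <- tables[tables$cluster == pr[2], measure]
    if (length(a) < 2 || length(b) < 2)
      stop("need at least two centrality values per cluster")
    ks <- suppressWarnings(stats::ks.test(a, b))
    data.frame(cluster_a = pr[1], cluster_b = pr[2], measure = measure,
               D = unname(ks$statistic), p_value = ks$p.value)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "n_tests") <- ncol(pairs)
  out
}
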