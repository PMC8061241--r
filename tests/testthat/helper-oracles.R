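# Independent oracles used across the suite. These deliberately use
# brute-force enumeration or textbook formulas, never the package's own
# algorithms.

# Minimal wss over all assignments of n points to k non-empty clusters
# (feasible only for tiny n).
brute_force_min_wss <- function(x, k) {
  n <- nrow(x)
  stopifnot(k == 2, n <= 14)
  best <- Inf
  best_assign <- NULL
  for (code in 1:(2^(n - 1) - 1)) {     # fix point 1 in cluster 1; no empties
    assign <- as.integer(intToBits(code))[seq_len(n)] + 1L
    wss <- 0
    for (c in 1:2) {
      pts <- x[assign == c, , drop = FALSE]
      wss <- wss + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    if (wss < best) { best <- wss; best_assign <- assign }
  }
  list(wss = best, assign = best_assign)
}

# All simple paths between every node pair of a weighted network with edge
# distance 1/|w|; returns shortest-path distances, closeness (reciprocal mean
# distance over reachable nodes) and betweenness (fractional tie counting).
path_metrics_oracle <- function(w, tol = 1e-9) {
  p <- nrow(w)
  dist_edge <- ifelse(w == 0, Inf, 1 / abs(w))
  diag(dist_edge) <- Inf
  # enumerate simple paths by DFS
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1]] <<- list(path = path, len = len); return() }
      for (u in seq_len(p)) {
        if (is.finite(dist_edge[v, u]) && !(u %in% path))
          walk(c(path, u), len + dist_edge[v, u])
      }
    }
    walk(s, 0)
    out
  }
  D <- matrix(Inf, p, p); diag(D) <- 0
  btw <- numeric(p)
  for (s in 1:(p - 1)) for (t in (s + 1):p) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, 0, "len")
    dmin <- min(lens)
    D[s, t] <- D[t, s] <- dmin
    shortest <- paths[lens <= dmin * (1 + tol)]
    for (v in seq_len(p)) {
      if (v == s || v == t) next
      on_path <- vapply(shortest, function(pp) v %in% pp$path, TRUE)
      btw[v] <- btw[v] + sum(on_path) / length(shortest)
    }
  }
  closeness <- sapply(seq_len(p), function(v) {
    d <- D[v, -v]; d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / mean(d)
  })
  list(distances = D, closeness = closeness, betweenness = btw)
}

# Random sparse symmetric weight matrix with zero diagonal.
random_weight_matrix <- function(p, edge_prob = 0.5) {
  w <- matrix(0, p, p)
  up <- which(upper.tri(w))
  on <- up[stats::runif(length(up)) < edge_prob]
  w[on] <- stats::runif(length(on), -0.9, 0.9)
  w <- w + t(w)
  w
}

# Partial correlation of items j,k by the residual-regression definition.
residual_pcor <- function(x, j, k) {
  rest <- setdiff(seq_len(ncol(x)), c(j, k))
  rj <- if (length(rest)) stats::residuals(stats::lm(x[, j] ~ x[, rest])) else x[, j]
  rk <- if (length(rest)) stats::residuals(stats::lm(x[, k] ~ x[, rest])) else x[, k]
  stats::cor(rj, rk)
}

# Edge-set F1 between a true and an estimated precision matrix.
edge_f1 <- function(true_omega, est_omega, tol = 1e-10) {
  tru <- abs(true_omega[upper.tri(true_omega)]) > tol
  est <- abs(est_omega[upper.tri(est_omega)]) > tol
  2 * sum(tru & est) / (sum(tru) + sum(est))
}

# A cluster_network wrapper around a bare weight matrix.
as_network <- function(w, cluster_id = 1L) {
  p <- nrow(w)
  diag(w) <- 0
  dimnames(w) <- list(paste0("item_", seq_len(p)), paste0("item_", seq_len(p)))
  structure(list(pcor = w,
                 item_labels = paste0("item_", seq_len(p)),
                 cluster_id = as.integer(cluster_id), n_members = NA_integer_,
                 constant_items = integer(), lambda = NA_real_,
                 selection_method = "fixed"),
            class = "cluster_network")
}
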