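#' Subtype respondents and estimate per-cluster symptom networks
#'
#' The full procedure in one fitting call: (1) per-person covariance
#' featurization of the ordinal responses around the item grand means;
#' (2) k-means (k-means++ seeding, restarts) over a range of cluster counts,
#' with a WSS-versus-k table for fit-versus-parsimony inspection;
#' (3) within each selected cluster, a semi-parametric Gaussian-copula
#' network fitted on that cluster's RAW responses (nonparanormal transform,
#' then EBIC-tuned graphical lasso, then partial correlations) -- never on
#' the covariance features; (4) node centralities, global density and
#' connectivity per cluster, and pairwise Kolmogorov-Smirnov comparisons of
#' the centrality distributions.
#'
#' @param responses n x p integer matrix (or data.frame) of ordinal
#'   responses, e.g. 1-5 Likert; no missing cells.
#' @param k number of clusters for the network stage. `NULL` (default) takes
#'   the sweep's elbow suggestion -- inspect the WSS table before trusting
#'   it, the choice deliberately involves judgement.
#' @param k_range contiguous range swept for the WSS table (default `2:8`).
#' @param n_restarts k-means++ restarts per k (default 20).
#' @param seed integer seed controlling all randomness in the fit.
#' @param standardize_features z-score the covariance features before
#'   clustering (default `FALSE`: clustering operates on raw cross-products).
#' @param min_cluster_n smallest cluster for which a network is estimated
#'   (default 50); smaller clusters are skipped with a recorded reason.
#' @param lambda_path,selection,ebic_gamma passed to [glasso_fit()].
#' @param max_iter Lloyd iteration cap.
#' @return object of class `distress_subtypes`: list with `k`, `sweep`
#'   (a `ksweep`), `clustering` (the `kmeans_fit` at `k`), `networks` (list
#'   of `cluster_network`, `NULL` where skipped), `skipped` (named reasons),
#'   `centrality` (data.frame), `connectivity` (data.frame), `ks`
#'   (data.frame over all measures), `cluster_summary` (n, mean/sd sum
#'   score per cluster), `grand_means`, `config`, `seed`.
#' @export
#' @examples
#' sim <- simulate_responses(make_default_specs(K = 2, p = 5, n_total = 250,
#'                                              skew_profile = "balanced"), seed = 3)
#' fit <- distress_subtypes(sim$responses, k = 2, k_range = 2:3,
#'                          n_restarts = 5, seed = 3)
#' fit
distress_subtypes <- function(responses, k = NULL, k_range = 2:8,
                              n_restarts = 20, seed = 1,
                              standardize_features = FALSE,
                              min_cluster_n = 50, lambda_path = NULL,
                              selection = c("ebic", "fixed"),
                              ebic_gamma = 0.5, max_iter = 300) {
  selection <- match.arg(selection)
  responses <- .check_responses(responses)
  stopifnot(all(k_range == seq(min(k_range), max(k_range))))
  feats <- person_cov_features(responses, standardize = standardize_features)
  sweep <- sweep_k(feats, min(k_range), max(k_range), n_restarts, seed, max_iter)
  if (is.null(k)) {
    k <- sweep$suggested_k
    if (is.na(k)) stop("k range too short for the elbow suggestion; pass k explicitly")
  }
  clustering <- if (as.character(k) %in% names(sweep$results))
    sweep$results[[as.character(k)]]
  else kmeans_fit(feats, k, n_restarts, seed, max_iter)
  sweep$selected_k <- k

  networks <- vector("list", k)
  skipped <- character(0)
  for (cl in seq_len(k)) {
    rows <- clustering$labels == cl
    if (sum(rows) < min_cluster_n) {
      skipped[as.character(cl)] <-
        sprintf("cluster %d has %d members, below the minimum of %d",
                cl, sum(rows), min_cluster_n)
      next
    }
    networks[[cl]] <- fit_cluster_network(responses[rows, , drop = FALSE],
                                          cluster_id = cl,
                                          lambda_path = lambda_path,
                                          selection = selection,
                                          ebic_gamma = ebic_gamma)
  }
  fitted_nets <- Filter(Negate(is.null), networks)

  centrality <- if (length(fitted_nets)) centrality_table(fitted_nets) else NULL
  connectivity <- if (length(fitted_nets)) do.call(rbind, lapply(fitted_nets, function(nt) {
    gc <- global_connectivity(nt)
    data.frame(cluster = nt$cluster_id, n = nt$n_members,
               density = gc$density, connectivity = gc$connectivity,
               n_edges = gc$n_edges)
  })) else NULL
  ks <- if (!is.null(centrality) && length(unique(centrality$cluster)) >= 2)
    do.call(rbind, lapply(c("strength", "closeness", "betweenness"),
                          function(m) ks_compare(centrality, m)))
  else NULL

  sumscore <- rowSums(responses)
  cluster_summary <- do.call(rbind, lapply(seq_len(k), function(cl) {
    s <- sumscore[clustering$labels == cl]
    data.frame(cluster = cl, n = length(s), mean_sumscore = mean(s),
               sd_sumscore = stats::sd(s))
  }))

  structure(list(k = k, sweep = sweep, clustering = clustering,
                 networks = networks, skipped = skipped,
                 centrality = centrality, connectivity = connectivity,
                 ks = ks, cluster_summary = cluster_summary,
                 grand_means = attr(feats, "grand_means"),
                 config = list(k = k, k_range = range(k_range),
                               n_restarts = n_restarts,
                               standardize_features = standardize_features,
                               min_cluster_n = min_cluster_n,
                               selection = selection, ebic_gamma = ebic_gamma,
                               max_iter = max_iter),
                 seed = seed,
                 call = match.call()),
            class = "distress_subtypes")
}

#' @export
print.distress_subtypes <- function(x, ...) {
  cat(sprintf("Distress subtypes: %d clusters over %d respondents (seed %d)\n\n",
              x$k, length(x$clustering$labels), x$seed))
  print(x$cluster_summary, row.names = FALSE, digits = 4)
  if (!is.null(x$connectivity)) {
    cat("\nGlobal network connectivity:\n")
    print(x$connectivity, row.names = FALSE, digits = 3)
  }
  if (length(x$skipped))
    cat("\nSkipped networks:\n ", paste(x$skipped, collapse = "\n  "), "\n")
  invisible(x)
}

#' @export
summary.distress_subtypes <- function(object, top_n = 3, ...) {
  structure(list(fit = object, top_n = top_n, report = report(object, top_n)),
            class = "summary.distress_subtypes")
}

#' @export
print.summary.distress_subtypes <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}

#' Markdown report of a fitted subtype model
#'
#' Per-cluster section with size, mean/sd sum score, density, connectivity
#' and the most central nodes per measure (mirroring the usual descriptive,
#' connectivity and top-centrality tables of symptom-network studies).
#'
#' @param x a `distress_subtypes` fit.
#' @param top_n how many top-central nodes to list per measure.
#' @return character vector of markdown lines.
#' @export
report <- function(x, top_n = 3) {
  stopifnot(inherits(x, "distress_subtypes"))
  lines <- c(sprintf("# Distress subtype report (k = %d, seed %d)", x$k, x$seed), "")
  lines <- c(lines, "## WSS by k", "",
             sprintf("    k = %d: wss = %.6g", x$sweep$table$k, x$sweep$table$wss), "")
  for (cl in seq_len(x$k)) {
    cs <- x$cluster_summary[x$cluster_summary$cluster == cl, ]
    lines <- c(lines, sprintf("## Cluster %d", cl),
               sprintf("- n = %d, sum score mean %.2f (sd %.2f)",
                       cs$n, cs$mean_sumscore, cs$sd_sumscore))
    net <- x$networks[[cl]]
    if (is.null(net)) {
      lines <- c(lines, sprintf("- network skipped: %s",
                                x$skipped[as.character(cl)]), "")
      next
    }
    gc <- global_connectivity(net)
    lines <- c(lines, sprintf("- density %.4f, connectivity %.3f (%d/%d edges)",
                              gc$density, gc$connectivity, gc$n_edges, gc$n_pairs))
    ct <- x$centrality[x$centrality$cluster == cl, ]
    for (m in c("strength", "closeness", "betweenness")) {
      pos <- ct[ct[[m]] > 0, ]
      if (!nrow(pos)) {
        lines <- c(lines, sprintf("- top %s: (none)", m))
      } else {
        top <- pos[order(-pos[[m]], pos$node), ][seq_len(min(top_n, nrow(pos))), ]
        lines <- c(lines, sprintf("- top %s: %s", m,
                                  paste(sprintf("%s (%.3f)", top$node, top[[m]]),
                                        collapse = ", ")))
      }
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
coef.distress_subtypes <- function(object, ...) {
  lapply(object$networks, function(net) if (is.null(net)) NULL else net$pcor)
}

#' Assign new respondents to fitted subtypes
#'
#' Featurizes new responses with the TRAINING grand means and assigns each
#' row to the nearest k-means centroid.
#'
#' @param object a `distress_subtypes` fit.
#' @param newdata n x p response matrix on the same items.
#' @param ... unused.
#' @return integer vector of cluster assignments.
#' @export
predict.distress_subtypes <- function(object, newdata, ...) {
  feats <- person_cov_features(newdata, means = object$grand_means,
                               standardize = FALSE)
  if (object$config$standardize_features)
    stop("prediction is not supported for fits with standardized features")
  d2 <- .dist2(unclass(feats), object$clustering$centroids)
  max.col(-d2, ties.method = "first")
}

#' Plot a fitted subtype model
#'
#' `type = "scree"` draws the WSS-versus-k curve; `type = "network"` draws
#' the partial-correlation matrix of one cluster as a signed image;
#' `type = "centrality"` draws per-cluster centrality profiles.
#'
#' @param x a `distress_subtypes` fit.
#' @param type which panel to draw.
#' @param cluster cluster id for `type = "network"`.
#' @param ... passed to the underlying base graphics call.
#' @return invisibly, `x`.
#' @export
plot.distress_subtypes <- function(x, type = c("scree", "network", "centrality"),
                                   cluster = 1, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    plot(x$sweep$table$k, x$sweep$table$wss, type = "b", xlab = "k",
         ylab = "within-cluster sum of squares", ...)
  } else if (type == "network") {
    net <- x$networks[[cluster]]
    if (is.null(net)) stop("no network was fitted for that cluster")
    p <- nrow(net$pcor)
    lim <- max(abs(net$pcor), 1e-12)
    image(seq_len(p), seq_len(p), t(net$pcor[p:1, ]), zlim = c(-lim, lim),
          col = grDevices::hcl.colors(65, "Blue-Red 3"), axes = FALSE,
          xlab = "", ylab = "",
          main = sprintf("Cluster %d partial correlations", cluster), ...)
    graphics::axis(1, seq_len(p), net$item_labels, las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(p), rev(net$item_labels), las = 2, cex.axis = 0.7)
  } else {
    ct <- x$centrality
    if (is.null(ct)) stop("no centrality table available")
    op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
    for (m in c("strength", "closeness", "betweenness")) {
      graphics::matplot(matrix(ct[[m]], ncol = length(unique(ct$cluster))),
                        type = "b", pch = 1, xlab = "node", ylab = m, ...)
    }
  }
  invisible(x)
}

#' Write a results bundle to a directory
#'
#' Writes every component of the fit as plain text: `labels.csv`,
#' `wss.tsv`, `sweep.json`, per-cluster `pcor_cluster_<i>.csv` and edge
#' lists `edges_cluster_<i>.tsv` (nonzero edges only), `centrality.tsv`,
#' `connectivity.tsv`, `ks_tests.tsv`, `cluster_summary.tsv`, `report.md`
#' and a `manifest.json` recording the configuration, seed and versions.
#' Identical fits produce byte-identical bundles.
#'
#' @param x a `distress_subtypes` fit.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "distress_subtypes"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name, sep) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       eol = "\n")
    paths <<- c(paths, path)
  }
  wr(data.frame(cluster = x$clustering$labels), "labels.csv", ",")
  wr(x$sweep$table, "wss.tsv", "\t")
  wr(x$cluster_summary, "cluster_summary.tsv", "\t")
  if (!is.null(x$centrality)) wr(x$centrality, "centrality.tsv", "\t")
  if (!is.null(x$connectivity)) wr(x$connectivity, "connectivity.tsv", "\t")
  if (!is.null(x$ks)) wr(x$ks, "ks_tests.tsv", "\t")
  for (cl in seq_len(x$k)) {
    net <- x$networks[[cl]]
    if (is.null(net)) next
    pc <- as.data.frame(net$pcor)
    wr(cbind(node = net$item_labels, pc), sprintf("pcor_cluster_%d.csv", cl), ",")
    idx <- which(upper.tri(net$pcor) & abs(net$pcor) > 1e-10, arr.ind = TRUE)
    edges <- data.frame(node_a = net$item_labels[idx[, 1]],
                        node_b = net$item_labels[idx[, 2]],
                        weight = net$pcor[idx])
    wr(edges, sprintf("edges_cluster_%d.tsv", cl), "\t")
  }
  rp <- file.path(dir, "report.md")
  writeLines(report(x), rp)
  paths <- c(paths, rp)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = x$seed, config = x$config,
                            k = x$k, suggested_k = x$sweep$suggested_k,
                            skipped = as.list(x$skipped),
                            package = "distressnet",
                            version = as.character(utils::packageVersion("distressnet"))),
                       manifest, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, manifest)
  sw <- file.path(dir, "sweep.json")
  jsonlite::write_json(list(table = x$sweep$table, selected_k = x$sweep$selected_k,
                            suggested_k = x$sweep$suggested_k),
                       sw, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, sw))
}
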