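#' k-means clustering with k-means++ seeding and restarts
#'
#' Lloyd's algorithm, seeded by k-means++ independently in each restart; the
#' restart with the lowest total within-cluster sum of squares is returned.
#' Should a cluster empty out during iteration, its centroid is reseeded at
#' the point farthest from its assigned centroid (recorded in the result).
#' Cluster identifiers are re-indexed in decreasing cluster size, so cluster
#' 1 is always the largest.
#'
#' @param features n x m numeric matrix (typically a
#'   [person_cov_features()] result).
#' @param k number of clusters, `1 <= k <= n`.
#' @param n_restarts independent k-means++ restarts (default 20).
#' @param seed integer RNG seed; results are deterministic given the seed.
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return object of class `kmeans_fit`: list with `k`, `labels` (1..k,
#'   cluster 1 largest), `centroids` (k x m), `wss` (total within-cluster sum
#'   of squares), `n_iter`, `seed`, `n_restarts`, `reseeds` (empty-cluster
#'   reseed count across the winning restart).
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 6), 20))
#' fit <- kmeans_fit(x, k = 2, n_restarts = 5, seed = 1)
#' table(fit$labels)
kmeans_fit <- function(features, k, n_restarts = 20, seed = 1, max_iter = 300) {
  x <- unclass(as.matrix(features))
  n <- nrow(x)
  stopifnot(is.numeric(x), n >= 1, n_restarts >= 1, max_iter >= 1)
  if (k < 1) stop("k must be at least 1")
  if (k > n) stop(sprintf("k = %d exceeds the number of respondents (%d)", k, n))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .lloyd(x, k, max_iter)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  # relabel so cluster sizes are decreasing (ties keep first-seen order)
  sizes <- tabulate(best$labels, nbins = k)
  ord <- order(-sizes, seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(k = k, labels = relabel[best$labels],
                 centroids = best$centroids[ord, , drop = FALSE],
                 wss = best$wss, n_iter = best$n_iter, seed = seed,
                 n_restarts = n_restarts, reseeds = best$reseeds),
            class = "kmeans_fit")
}

# squared Euclidean distances from every row of x to every centroid
.dist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1), , drop = FALSE]
  if (k > 1) {
    d2 <- .dist2(x, centers)[, 1]
    for (j in 2:k) {
      tot <- sum(d2)
      i <- if (tot <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2 / tot)
      centers <- rbind(centers, x[i, ])
      d2 <- pmin(d2, .dist2(x, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

.lloyd <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- .kmeanspp_init(x, k)
  labels <- integer(n)
  reseeds <- 0L
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    for (c in seq_len(k)) {           # empty cluster: reseed at farthest point
      if (!any(new_labels == c)) {
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        centers[c, ] <- x[far, ]
        new_labels[far] <- c
        reseeds <- reseeds + 1L
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (c in seq_len(k))
      centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
  }
  wss <- sum((x - centers[labels, , drop = FALSE])^2)
  list(labels = labels, centroids = centers, wss = wss, n_iter = it,
       reseeds = reseeds)
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat(sprintf("k-means fit: k = %d, wss = %.4g, %d restart(s), seed %d\n",
              x$k, x$wss, x$n_restarts, x$seed))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Sweep k-means over a range of cluster counts
#'
#' Fits [kmeans_fit()] for each `k` in `k_min..k_max` and tabulates the
#' within-cluster sum of squares, supporting the usual fit-versus-parsimony
#' inspection. The choice of `k` ultimately involves judgement; an elbow
#' suggestion (the `k` maximising the second difference of the WSS curve) is
#' reported but nothing is selected automatically.
#'
#' @inheritParams kmeans_fit
#' @param k_min,k_max contiguous range of cluster counts.
#' @return object of class `ksweep`: list with `results` (named list of
#'   `kmeans_fit`, names `"2"`, `"3"`, ...), `table` (data.frame k, wss,
#'   n_iter), `suggested_k` (elbow heuristic, `NA` when the range is too
#'   short) and `selected_k` (`NULL`; set by the caller).
#' @export
sweep_k <- function(features, k_min = 2, k_max = 8, n_restarts = 20, seed = 1,
                    max_iter = 300) {
  n <- nrow(as.matrix(features))
  stopifnot(k_min >= 1, k_min <= k_max)
  if (k_max > n) stop("k_max exceeds the number of respondents")
  ks <- k_min:k_max
  results <- lapply(seq_along(ks), function(i)
    kmeans_fit(features, ks[i], n_restarts, seed + i - 1L, max_iter))
  names(results) <- as.character(ks)
  wss <- vapply(results, `[[`, 0, "wss")
  if (any(diff(wss) > 0))
    warning("WSS not monotone in k; consider more restarts")
  suggested <- NA_integer_
  if (length(ks) >= 3) {
    d2 <- diff(diff(wss))                 # second difference of the curve
    suggested <- ks[which.max(d2) + 1L]
  }
  structure(list(results = results,
                 table = data.frame(k = ks, wss = unname(wss),
                                    n_iter = vapply(results, `[[`, 0L, "n_iter")),
                 suggested_k = suggested, selected_k = NULL,
                 seed = seed),
            class = "ksweep")
}

#' @export
print.ksweep <- function(x, ...) {
  cat("k-means sweep (WSS by k):\n")
  print(x$table, row.names = FALSE)
  if (!is.na(x$suggested_k))
    cat(sprintf("Elbow suggestion (max second difference): k = %d\n", x$suggested_k))
  if (!is.null(x$selected_k))
    cat(sprintf("Selected: k = %d\n", x$selected_k))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same units; 1 for
#' identical partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b integer/factor vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
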