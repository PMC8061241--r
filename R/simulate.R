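#' Construct default cluster specifications for simulated distress data
#'
#' Builds `K` latent-Gaussian cluster specifications emulating a general
#' population assessed with a p-item ordinal symptom scale: clusters differ
#' both in overall severity (increasing latent location) and in their
#' inter-item conditional dependence structure (distinct sparse precision
#' matrices). Under the `floor_heavy` profile thresholds sit high on the
#' latent scale so the lowest-severity cluster answers mostly 1, mirroring
#' the strong floor effects of psychopathology items in community samples.
#'
#' Each precision matrix is built diagonally dominant
#' (`diag = 1 + sum(|off-diagonal|)` per row), which guarantees positive
#' definiteness; should a numerically non-PD matrix ever arise, escalating
#' diagonal loading (eps = 1e-6 * trace/p, times 10 per retry, 3 tries) is
#' applied and recorded in the spec's `loading` field.
#'
#' @param K number of clusters (>= 1).
#' @param p number of items (>= 2).
#' @param sparsity probability in (0,1) that an item pair is conditionally
#'   dependent (carries a precision off-diagonal).
#' @param skew_profile `"floor_heavy"` (population-like right skew; default)
#'   or `"balanced"` (thresholds give roughly equal category shares for a
#'   zero-mean cluster).
#' @param seed integer RNG seed; identical arguments give identical specs.
#' @param sizes optional integer vector of cluster sizes (length `K`). The
#'   default splits `n_total` respondents geometrically so cluster 1 is the
#'   largest and cluster `K` the smallest, as in general-population severity
#'   strata.
#' @param n_total total respondents used when `sizes` is `NULL`.
#' @param separation latent-location gap between consecutive severity strata,
#'   in latent SD-scale units.
#' @param edge_weight absolute partial-correlation magnitude carried by each
#'   item pair on the precision support (shrunk automatically if a draw
#'   cannot be made positive definite).
#' @param n_levels number of ordinal response levels L (default 5).
#' @return list of `cluster_spec` objects with fields `mean_shift`
#'   (length-p latent locations), `precision` (p x p SPD matrix), `size`,
#'   `thresholds` (p x (L-1), strictly increasing per row), `loading`
#'   (diagonal loading applied, 0 if none) and `cluster` (index).
#' @seealso [simulate_responses()]
#' @export
#' @examples
#' specs <- make_default_specs(K = 3, p = 5, seed = 1, n_total = 300)
#' sapply(specs, `[[`, "size")
make_default_specs <- function(K = 5, p = 10, sparsity = 0.3,
                               skew_profile = c("floor_heavy", "balanced"),
                               seed = 1, sizes = NULL, n_total = 2000,
                               separation = 3, edge_weight = 0.3,
                               n_levels = 5L) {
  stopifnot(K >= 1, p >= 2, sparsity > 0, sparsity < 1, n_levels >= 2)
  skew_profile <- match.arg(skew_profile)
  if (is.null(sizes)) {
    w <- 0.55^(seq_len(K) - 1)
    sizes <- pmax(1L, as.integer(round(n_total * w / sum(w))))
    sizes[1] <- sizes[1] + (n_total - sum(sizes))
  }
  stopifnot(length(sizes) == K, all(sizes >= 1))

  set.seed(seed)
  specs <- vector("list", K)
  for (cl in seq_len(K)) {
    # Severity location: increasing base level, modulated by a cluster-specific
    # item-domain emphasis pattern (alternating +/-50% blocks of width
    # 2^(cl-2)). Uniform shifts would leave distinct severity strata with
    # near-identical deviation cross-products (the featurization is blind to
    # reflections around the grand mean); emphasis patterns break that
    # symmetry, and mirror the fact that real subtypes weight symptom domains
    # differently, not just overall severity.
    base <- (cl - 1) * separation
    emphasis <- if (cl == 1) rep(0, p)
                else (-1)^floor((seq_len(p) - 1) / 2^(cl - 2))
    shift <- base * (1 + 0.5 * emphasis) + stats::runif(p, -0.1, 0.1)
    omega <- .random_precision(p, sparsity, edge_weight,
                               prob_positive = if (cl %% 2 == 0) 0.35 else 0.85)
    thr <- .default_thresholds(p, n_levels, skew_profile, K, separation)
    specs[[cl]] <- new_cluster_spec(mean_shift = shift,
                                    precision = omega$precision,
                                    size = sizes[cl], thresholds = thr,
                                    loading = omega$loading, cluster = cl)
  }
  specs
}

# Sparse symmetric precision whose off-diagonal support carries partial
# correlations of magnitude edge_weight, rescaled so the implied latent
# covariance has unit diagonal (thresholds and separations are then in
# latent-SD units and the partial correlations are untouched by the
# rescaling). Non-PD draws get escalating diagonal loading; if that cannot
# repair the matrix the edge magnitude is shrunk and the construction
# restarted.
.random_precision <- function(p, sparsity, edge_weight, prob_positive) {
  n_pairs <- p * (p - 1) / 2
  on_edge <- stats::runif(n_pairs) < sparsity
  if (!any(on_edge)) on_edge[sample.int(n_pairs, 1)] <- TRUE
  sgn <- ifelse(stats::runif(n_pairs) < prob_positive, 1, -1)
  loading <- 0
  r <- edge_weight
  repeat {
    w <- ifelse(on_edge, -sgn * r, 0)   # pcor_jk = -omega_jk on unit diagonal
    omega <- matrix(0, p, p)
    omega[upper.tri(omega)] <- w
    omega <- omega + t(omega)
    diag(omega) <- 1
    eps <- 1e-6 * sum(diag(omega)) / p
    ok <- FALSE
    for (try in 0:3) {
      if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) > 1e-4) {
        ok <- TRUE; break
      }
      if (try == 3) break
      diag(omega) <- diag(omega) + eps
      loading <- loading + eps
      eps <- eps * 10
    }
    if (ok) break
    r <- 0.8 * r                        # deterministic fallback, support kept
    loading <- 0
  }
  # rescale so solve(omega) has unit diagonal (leaves pcor unchanged)
  d <- sqrt(diag(solve(omega)))
  omega <- omega * outer(d, d)
  omega <- (omega + t(omega)) / 2
  list(precision = omega, loading = loading, edge_pcor = r)
}

# Thresholds span the latent severity range (K - 1) * separation so that
# every severity stratum occupies a distinct response profile instead of
# piling up in the top category.
.default_thresholds <- function(p, L, skew_profile, K, separation) {
  base <- switch(skew_profile,
    # cutpoints start well above the lowest (zero-mean) cluster, which
    # therefore answers mostly 1, and step by the cluster separation
    floor_heavy = seq(2 / 3 * separation, by = separation, length.out = L - 1),
    # cutpoints centred on the severity midpoint, spread to cover the pooled
    # latent distribution, so overall category shares are roughly even
    balanced = {
      mid <- (K - 1) * separation / 2
      spread <- max(1, (K - 1) * separation / 2.5)
      mid + spread * stats::qnorm(seq_len(L - 1) / L)
    })
  matrix(rep(base, each = p), nrow = p)
}

#' Create and validate a cluster specification
#'
#' @param mean_shift length-p numeric latent locations.
#' @param precision p x p symmetric positive-definite matrix.
#' @param size positive integer number of respondents.
#' @param thresholds p x (L-1) matrix, strictly increasing within each row.
#' @param loading diagonal loading that was applied during construction.
#' @param cluster integer identifier.
#' @return object of class `cluster_spec`.
#' @export
new_cluster_spec <- function(mean_shift, precision, size, thresholds,
                             loading = 0, cluster = NA_integer_) {
  p <- length(mean_shift)
  stopifnot(is.matrix(precision), nrow(precision) == p, ncol(precision) == p)
  if (max(abs(precision - t(precision))) > 1e-10)
    stop("precision must be symmetric")
  ev <- eigen((precision + t(precision)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision must be positive definite")
  stopifnot(length(size) == 1, size >= 1, is.matrix(thresholds),
            nrow(thresholds) == p)
  if (ncol(thresholds) > 1 && any(apply(thresholds, 1, diff) <= 0))
    stop("thresholds must be strictly increasing within each item")
  structure(list(mean_shift = as.numeric(mean_shift),
                 precision = precision, size = as.integer(size),
                 thresholds = thresholds, loading = loading,
                 cluster = as.integer(cluster)),
            class = "cluster_spec")
}

#' Draw multivariate normal data parameterised by a precision matrix
#'
#' Samples `n` vectors from N(mu, solve(omega)) using the Cholesky factor of
#' the precision matrix (no explicit covariance inversion).
#'
#' @param n number of draws.
#' @param omega p x p symmetric positive-definite precision matrix.
#' @param mu length-p mean (default zero).
#' @return n x p numeric matrix.
#' @export
rmvn_precision <- function(n, omega, mu = rep(0, nrow(omega))) {
  p <- nrow(omega)
  U <- tryCatch(chol(omega), error = function(e)
    stop("precision matrix is not positive definite", call. = FALSE))
  # omega = U'U  =>  x = U^{-1} w has covariance solve(omega)
  w <- matrix(stats::rnorm(n * p), p, n)
  t(backsolve(U, w)) + matrix(mu, n, p, byrow = TRUE)
}

#' Simulate ordinal questionnaire responses from cluster specifications
#'
#' For each cluster spec, draws `size` latent vectors from the Gaussian with
#' mean `mean_shift` and covariance `solve(precision)`, discretises item `j`
#' by its threshold row into categories `1..L`, concatenates the clusters and
#' shuffles the rows (so cluster order cannot leak into downstream
#' initialisation). The pre-discretisation latents are returned alongside,
#' which makes parameter-recovery checks possible.
#'
#' @param specs list of `cluster_spec` objects (see [make_default_specs()]).
#' @param seed integer RNG seed; identical seed gives bit-identical output.
#' @return object of class `distress_sim`: list with `responses` (n x p
#'   integer matrix, columns `item_1..item_p`), `true_labels` (length n,
#'   aligned to rows), `latents` (n x p, pre-discretisation), `specs`, `seed`.
#' @export
#' @examples
#' sim <- simulate_responses(make_default_specs(K = 2, p = 4, n_total = 100), seed = 7)
#' table(sim$true_labels)
simulate_responses <- function(specs, seed) {
  if (inherits(specs, "cluster_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, TRUE, "cluster_spec")))
  p <- length(specs[[1]]$mean_shift)
  set.seed(seed)
  resp <- lat <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (length(s$mean_shift) != p) stop("specs disagree on item count")
    z <- tryCatch(rmvn_precision(s$size, s$precision, s$mean_shift),
                  error = function(e)
                    stop(sprintf("cluster %d: singular precision", i), call. = FALSE))
    x <- matrix(0L, s$size, p)
    for (j in seq_len(p))
      x[, j] <- findInterval(z[, j], s$thresholds[j, ]) + 1L
    resp[[i]] <- x
    lat[[i]] <- z
  }
  responses <- do.call(rbind, resp)
  latents <- do.call(rbind, lat)
  labels <- rep(seq_along(specs), vapply(specs, `[[`, 1L, "size"))
  ord <- sample.int(nrow(responses))
  responses <- responses[ord, , drop = FALSE]
  colnames(responses) <- paste0("item_", seq_len(p))
  structure(list(responses = responses,
                 true_labels = labels[ord],
                 latents = latents[ord, , drop = FALSE],
                 specs = specs, seed = seed),
            class = "distress_sim")
}

#' @export
print.distress_sim <- function(x, ...) {
  cat(sprintf("Simulated ordinal responses: %d respondents x %d items, %d clusters (seed %d)\n",
              nrow(x$responses), ncol(x$responses), length(x$specs), x$seed))
  print(table(cluster = x$true_labels))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `responses.csv` (header `item_1..item_p`, one respondent per row),
#' `labels.csv` (one column `cluster`) and `specs.json` under `dir`.
#'
#' @param sim a `distress_sim` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "distress_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("responses.csv", "labels.csv", "specs.json"))
  utils::write.csv(as.data.frame(sim$responses), paths[1], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(cluster = sim$true_labels), paths[2],
                   row.names = FALSE, quote = FALSE)
  specs_json <- lapply(sim$specs, function(s)
    list(cluster = s$cluster, size = s$size, mean_shift = s$mean_shift,
         precision = s$precision, thresholds = s$thresholds,
         loading = s$loading))
  jsonlite::write_json(specs_json, paths[3], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read an ordinal response matrix from CSV
#'
#' Expects the layout written by [write_simulation()]: a header row of item
#' labels and one respondent per row of integer responses.
#'
#' @param path CSV file path.
#' @return integer matrix with item labels as column names.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  m
}
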