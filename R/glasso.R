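#' Graphical lasso: L1-penalised sparse precision estimation
#'
#' Solves `max_Theta log det(Theta) - tr(S Theta) - rho * ||Theta||_{1,off}`
#' by block coordinate descent on the estimated covariance (the classic
#' graphical-lasso scheme: each row/column update is a lasso regression
#' solved by inner coordinate descent). Only off-diagonal entries are
#' penalised. At `rho = 0` the unpenalised maximum-likelihood solution --
#' the direct inverse of `S` -- is returned.
#'
#' @param S p x p sample covariance or correlation matrix (symmetric).
#' @param rho scalar penalty `>= 0`, or a p x p matrix of per-element
#'   penalties (used e.g. to refit without penalty on a fixed support while
#'   excluding all other edges).
#' @param tol relative convergence tolerance on the covariance iterate.
#' @param max_iter outer sweep cap.
#' @return list with `omega` (p x p precision estimate, symmetric, exact
#'   zeros off the selected support), `w` (its inverse, the fitted
#'   covariance), `rho`, `converged`, `n_iter`.
#' @references Friedman, Hastie and Tibshirani (2008), Biostatistics 9(3):
#'   sparse inverse covariance estimation with the graphical lasso.
#' @export
glasso_precision <- function(S, rho, tol = 1e-6, max_iter = 200) {
  p <- nrow(S)
  stopifnot(is.matrix(S), ncol(S) == p, all(rho >= 0))
  S <- (S + t(S)) / 2
  if (all(rho == 0)) {
    omega <- solve(S)
    omega <- (omega + t(omega)) / 2
    return(list(omega = omega, w = S, rho = 0, converged = TRUE, n_iter = 0L))
  }
  rho_mat <- if (is.matrix(rho)) rho else matrix(rho, p, p)
  W <- S
  B <- matrix(0, p, p)                    # lasso coefficients per column block
  thr <- tol * max(mean(abs(S[upper.tri(S)])), .Machine$double.eps)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[idx, j]
      rho_j <- rho_mat[idx, j]
      for (sweep in seq_len(500)) {       # inner lasso coordinate descent
        delta_max <- 0
        for (k in seq_along(idx)) {
          r_k <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          b_new <- .soft(r_k, rho_j[k]) / W11[k, k]
          delta_max <- max(delta_max, abs(b_new - beta[k]))
          beta[k] <- b_new
        }
        if (delta_max < thr / 10) break
      }
      B[idx, j] <- beta
      w12 <- drop(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < thr) { converged <- TRUE; break }
  }
  omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    beta <- B[idx, j]
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    omega[j, j] <- theta_jj
    omega[idx, j] <- -beta * theta_jj
  }
  # support is symmetric by construction; average out numerical asymmetry
  omega <- (omega + t(omega)) / 2
  dimnames(omega) <- dimnames(S)
  list(omega = omega, w = W, rho = rho, converged = converged, n_iter = it)
}

.soft <- function(x, t) sign(x) * max(abs(x) - t, 0)

#' Fit a sparse Gaussian graphical model along a penalty path
#'
#' Runs [glasso_precision()] on the correlation matrix of (already
#' transformed) data over a path of penalties and selects one by the
#' extended BIC,
#' `EBIC(rho) = -n [log det(Theta) - tr(S Theta)] + E log(n) + 4 gamma E log(p)`,
#' with `E` the number of selected edges. The likelihood entering the EBIC
#' is that of the unpenalised maximum-likelihood refit on the selected
#' support (selection and estimation decoupled): scoring the shrunken
#' penalised estimates instead makes the criterion keep rewarding smaller
#' penalties at large n and systematically over-selects. Estimation is
#' always on the correlation scale, so the penalty has the same meaning
#' across clusters and the resulting partial correlations are scale-free.
#'
#' @param transformed n x p numeric matrix (e.g. [npn_transform()] output).
#' @param lambda_path decreasing vector of penalties. Default: 30
#'   log-spaced values from `lambda_max` (the largest absolute off-diagonal
#'   correlation, at which the selected graph is empty) down to
#'   `0.01 * lambda_max`.
#' @param selection `"ebic"` (default) or `"fixed"`; with `"fixed"` the first
#'   element of `lambda_path` is used as-is.
#' @param ebic_gamma EBIC hyperparameter in `[0, 1]`; 0.5 is the usual
#'   conservative default for psychometric networks.
#' @param n_lambda path length when `lambda_path` is `NULL`.
#' @return object of class `precision_estimate`: list with `omega`, `lambda`,
#'   `lambda_path`, `ebic` (per path point, `NA` under `"fixed"`),
#'   `selection_method`, `ebic_gamma`, `n`, `S` (the correlation matrix
#'   used), `path_edges` (edge counts along the path).
#' @export
glasso_fit <- function(transformed, lambda_path = NULL,
                       selection = c("ebic", "fixed"), ebic_gamma = 0.5,
                       n_lambda = 30) {
  selection <- match.arg(selection)
  x <- as.matrix(transformed)
  n <- nrow(x); p <- ncol(x)
  keep <- apply(x, 2, stats::sd) > 0
  S <- diag(p)
  S[keep, keep] <- stats::cor(x[, keep, drop = FALSE])
  dimnames(S) <- list(colnames(x), colnames(x))
  if (is.null(lambda_path)) {
    lambda_max <- max(abs(S[upper.tri(S)]))
    if (lambda_max <= 0) lambda_max <- 0.1
    lambda_path <- exp(seq(log(lambda_max), log(0.01 * lambda_max),
                           length.out = n_lambda))
  }
  stopifnot(length(lambda_path) >= 1, all(lambda_path >= 0))
  if (selection == "fixed") {
    fit <- glasso_precision(S, lambda_path[1])
    if (!fit$converged) stop("graphical lasso did not converge at the fixed penalty")
    return(.new_precision_estimate(fit$omega, lambda_path[1], lambda_path,
                                   rep(NA_real_, length(lambda_path)),
                                   "fixed", ebic_gamma, n, S,
                                   .edge_count(fit$omega)))
  }
  fits <- vector("list", length(lambda_path))
  ebic <- rep(NA_real_, length(lambda_path))
  edges <- rep(NA_integer_, length(lambda_path))
  prev_support <- NULL
  prev_ll <- NULL
  for (i in seq_along(lambda_path)) {
    fit <- tryCatch(glasso_precision(S, lambda_path[i]), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning(sprintf("dropping non-converged path point lambda = %.4g",
                      lambda_path[i]))
      next
    }
    support <- abs(fit$omega) > 1e-10
    E <- .edge_count(fit$omega)
    if (identical(support, prev_support)) {
      ll <- prev_ll
    } else {
      ll <- .support_loglik(S, support)
      prev_support <- support
      prev_ll <- ll
    }
    ebic[i] <- -n * ll + E * log(n) + 4 * ebic_gamma * E * log(p)
    edges[i] <- E
    fits[[i]] <- fit
  }
  if (all(is.na(ebic))) stop("graphical lasso failed along the entire penalty path")
  best <- which.min(ebic)
  .new_precision_estimate(fits[[best]]$omega, lambda_path[best], lambda_path,
                          ebic, "ebic", ebic_gamma, n, S, edges)
}

.edge_count <- function(omega, tol = 1e-10)
  sum(abs(omega[upper.tri(omega)]) > tol)

# Gaussian profile log-likelihood term of the ML precision refit restricted
# to a support: unpenalised on the support, all other edges excluded. A small
# ridge stabilises the refit -- with near-duplicate items (common in heavily
# floored ordinal clusters) S is singular and the constrained MLE need not
# exist; the same ridge enters every candidate support, so the EBIC ranking
# is unaffected.
.support_loglik <- function(S, support) {
  p <- nrow(S)
  S_r <- S + diag(1e-3 * mean(diag(S)), p)
  rho_mat <- ifelse(support, 0, 10 * max(abs(S_r)))
  diag(rho_mat) <- 0
  refit <- glasso_precision(S_r, rho_mat, max_iter = 100)
  as.numeric(determinant(refit$omega, logarithm = TRUE)$modulus -
               sum(S_r * refit$omega))
}

.new_precision_estimate <- function(omega, lambda, lambda_path, ebic,
                                    selection_method, ebic_gamma, n, S,
                                    path_edges) {
  structure(list(omega = omega, lambda = lambda, lambda_path = lambda_path,
                 ebic = ebic, selection_method = selection_method,
                 ebic_gamma = ebic_gamma, n = n, S = S,
                 path_edges = path_edges),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("Sparse precision estimate: p = %d, n = %d, lambda = %.4g (%s), %d edge(s)\n",
              nrow(x$omega), x$n, x$lambda, x$selection_method,
              .edge_count(x$omega)))
  invisible(x)
}

#' Convert a precision estimate to a partial-correlation network
#'
#' Standardises the precision matrix into partial correlations,
#' `pcor_jk = -omega_jk / sqrt(omega_jj * omega_kk)` for `j != k`, zero on
#' the diagonal. Items flagged as constant within the cluster get all-zero
#' rows/columns, keeping node sets comparable across clusters.
#'
#' @param est a `precision_estimate` (or a plain precision matrix).
#' @param item_labels node labels (default from the matrix).
#' @param cluster_id integer identifier carried into the result.
#' @param n_members number of respondents behind the estimate.
#' @param constant_items indices whose edges are zeroed and flagged.
#' @return object of class `cluster_network`: list with `pcor` (p x p,
#'   symmetric, zero diagonal, entries in `[-1, 1]`), `item_labels`,
#'   `cluster_id`, `n_members`, `constant_items`, and the estimation
#'   metadata `lambda`/`selection_method`.
#' @export
precision_to_pcor <- function(est, item_labels = NULL, cluster_id = NA_integer_,
                              n_members = NA_integer_, constant_items = integer()) {
  omega <- if (inherits(est, "precision_estimate")) est$omega else as.matrix(est)
  p <- nrow(omega)
  d <- diag(omega)
  if (any(d <= 0)) stop("precision diagonal must be strictly positive")
  pcor <- -omega / sqrt(outer(d, d))
  diag(pcor) <- 0
  if (length(constant_items)) {
    pcor[constant_items, ] <- 0
    pcor[, constant_items] <- 0
  }
  if (is.null(item_labels))
    item_labels <- colnames(omega) %||% paste0("item_", seq_len(p))
  dimnames(pcor) <- list(item_labels, item_labels)
  structure(list(pcor = pcor, item_labels = item_labels,
                 cluster_id = as.integer(cluster_id),
                 n_members = as.integer(n_members),
                 constant_items = as.integer(constant_items),
                 lambda = if (inherits(est, "precision_estimate")) est$lambda else NA_real_,
                 selection_method = if (inherits(est, "precision_estimate"))
                   est$selection_method else "fixed"),
            class = "cluster_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cluster_network <- function(x, ...) {
  E <- .edge_count(x$pcor)
  cat(sprintf("Partial-correlation network: %d nodes, %d edge(s)%s%s\n",
              nrow(x$pcor), E,
              if (!is.na(x$cluster_id)) sprintf(", cluster %d", x$cluster_id) else "",
              if (!is.na(x$n_members)) sprintf(" (n = %d)", x$n_members) else ""))
  if (length(x$constant_items))
    cat("Constant items (edges zeroed):",
        paste(x$item_labels[x$constant_items], collapse = ", "), "\n")
  invisible(x)
}

#' Estimate a cluster's symptom network from raw ordinal responses
#'
#' The per-cluster estimation stage in one call: nonparanormal transform of
#' the cluster's raw responses, EBIC-tuned graphical lasso on the resulting
#' correlation matrix, conversion to partial correlations.
#'
#' @param responses n x p raw ordinal responses of the cluster's members.
#' @param cluster_id integer identifier.
#' @param min_n minimum rows required (default 10).
#' @inheritParams glasso_fit
#' @return a `cluster_network` (see [precision_to_pcor()]).
#' @export
fit_cluster_network <- function(responses, cluster_id = NA_integer_,
                                lambda_path = NULL,
                                selection = c("ebic", "fixed"),
                                ebic_gamma = 0.5, min_n = 10) {
  z <- npn_transform(responses, min_n = min_n)
  est <- glasso_fit(z, lambda_path = lambda_path, selection = selection,
                    ebic_gamma = ebic_gamma)
  precision_to_pcor(est, item_labels = colnames(z), cluster_id = cluster_id,
                    n_members = nrow(z),
                    constant_items = attr(z, "constant_items"))
}
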