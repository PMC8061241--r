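#' Grand means of questionnaire items
#'
#' Column means of the response matrix: the whole-sample average response for
#' each item, the reference point around which per-person covariation is
#' measured.
#'
#' @param data n x p numeric (ordinal) response matrix, no missing cells.
#' @return length-p numeric vector, named by item.
#' @export
grand_means <- function(data) {
  data <- .check_responses(data)
  colMeans(data)
}

.check_responses <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  stopifnot(is.matrix(data), is.numeric(data))
  if (anyNA(data)) stop("response matrix must have no missing cells")
  if (is.null(colnames(data)))
    colnames(data) <- paste0("item_", seq_len(ncol(data)))
  data
}

#' Per-person covariance features around the grand means
#'
#' Represents respondent `i` by the upper off-diagonal entries of their
#' deviation outer product: for each item pair `j < k`, the cross-product
#' `(x_ij - mean_j) * (x_ik - mean_k)`. These m = p(p-1)/2 entries form a
#' rough per-person estimate of a sample covariance matrix around the item
#' grand means (45 entries for a 10-item scale); averaging a feature column
#' over respondents recovers the biased sample covariance of that item pair.
#' Squared-deviation (diagonal) terms are excluded.
#'
#' @param data n x p response matrix.
#' @param means optional length-p grand means; computed from `data` when
#'   omitted (pass the training means when featurizing new respondents).
#' @param standardize if `TRUE`, z-score the feature columns. Off by default:
#'   the raw cross-products are the clustering space.
#' @return object of class `feature_matrix`: the n x m numeric matrix with
#'   columns `cov_j_k` (pair order (1,2),(1,3),...,(1,p),(2,3),...), plus
#'   attributes `pair_index` (m x 2), `grand_means` and `standardized`.
#' @export
#' @examples
#' x <- rbind(c(1, 2, 3), c(3, 4, 5))
#' person_cov_features(x)  # both rows (1, 1, 1)
person_cov_features <- function(data, means = NULL, standardize = FALSE) {
  data <- .check_responses(data)
  p <- ncol(data)
  stopifnot(p >= 2)
  if (is.null(means)) means <- colMeans(data)
  if (length(means) != p)
    stop(sprintf("means has length %d but data has %d items", length(means), p))
  dev <- sweep(data, 2, means)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)         # col-major j<k
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]  # row-major
  feats <- dev[, pairs[, 1], drop = FALSE] * dev[, pairs[, 2], drop = FALSE]
  colnames(feats) <- paste0("cov_", pairs[, 1], "_", pairs[, 2])
  if (standardize) {
    sds <- apply(feats, 2, stats::sd)
    sds[sds == 0] <- 1
    feats <- scale(feats, scale = sds)
    attr(feats, "scaled:center") <- NULL
    attr(feats, "scaled:scale") <- NULL
  }
  structure(feats,
            pair_index = unname(pairs),
            grand_means = stats::setNames(as.numeric(means), colnames(data)),
            standardized = standardize,
            class = c("feature_matrix", "matrix", "array"))
}

#' Write a feature matrix plus sidecar metadata
#'
#' Writes the features as CSV (`cov_j_k` columns) and a JSON sidecar holding
#' the grand means and the item-pair index.
#'
#' @param feats a `feature_matrix`.
#' @param path CSV path; the sidecar gets the extension `.json`.
#' @return invisibly, the two paths.
#' @export
write_features <- function(feats, path) {
  stopifnot(inherits(feats, "feature_matrix"))
  utils::write.csv(as.data.frame(unclass(feats)), path, row.names = FALSE,
                   quote = FALSE)
  side <- sub("\\.csv$", "", path)
  side <- paste0(side, ".json")
  jsonlite::write_json(list(grand_means = attr(feats, "grand_means"),
                            pair_index = attr(feats, "pair_index"),
                            standardized = attr(feats, "standardized")),
                       side, digits = NA, auto_unbox = TRUE)
  invisible(c(path, side))
}
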