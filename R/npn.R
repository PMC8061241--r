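#' Nonparanormal (Gaussian-copula) transform via shrunken empirical CDFs
#'
#' Estimates, per item, the monotone map under which the data are assumed
#' multivariate normal: observations are replaced by standard-normal
#' quantiles of their shrunken empirical CDF. Midranks handle the heavy ties
#' of Likert data; the ECDF is winsorised to `[delta_n, 1 - delta_n]` with
#' the truncation constant
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))`,
#' which controls the tails of the estimated transform. Because the map
#' depends on the data only through ranks, any strictly increasing per-item
#' deformation of the input leaves the output unchanged.
#'
#' @param data n x p numeric matrix (ordinal or continuous), no missing
#'   cells.
#' @param standardize if `TRUE` (default) each transformed column is centred
#'   and scaled to unit variance.
#' @param min_n minimum rows required (default 10); below this the rank-based
#'   transform is too coarse to support estimation.
#' @return n x p numeric matrix with attributes `delta_n`, `n_used` and
#'   `constant_items` (indices of zero-variance input columns, which are
#'   returned as all-zero and must be excluded from dependence estimation).
#' @references Liu, Lafferty and Wasserman (2009), JMLR 10: the nonparanormal
#'   semiparametric graphical model.
#' @export
#' @examples
#' x <- matrix(sample(1:5, 200, TRUE), 50, 4)
#' z <- npn_transform(x)
#' round(colMeans(z), 10)
npn_transform <- function(data, standardize = TRUE, min_n = 10) {
  data <- .check_responses(data)
  n <- nrow(data)
  if (n < min_n)
    stop(sprintf("need at least %d rows for the nonparanormal transform, got %d",
                 min_n, n))
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  constant <- which(apply(data, 2, function(col) min(col) == max(col)))
  out <- apply(data, 2, function(col) {
    u <- rank(col, ties.method = "average") / n
    stats::qnorm(pmin(pmax(u, delta), 1 - delta))
  })
  if (standardize) {
    out <- scale(out)
    attr(out, "scaled:center") <- NULL
    attr(out, "scaled:scale") <- NULL
  }
  if (length(constant)) out[, constant] <- 0
  dimnames(out) <- dimnames(data)
  structure(out, delta_n = delta, n_used = n,
            constant_items = as.integer(constant))
}
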