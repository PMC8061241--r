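test_that("a saturating penalty empties the network", {
  set.seed(1)
  x <- matrix(rnorm(200 * 4), 200, 4)
  S <- cor(x)
  rho <- max(abs(S[upper.tri(S)]))
  fit <- glasso_precision(S, rho * 1.001)
  off <- fit$omega[upper.tri(fit$omega)]
  expect_true(all(abs(off) < 1e-10))
  expect_true(all(diag(fit$omega) > 0))
})

test_that("lambda = 0 recovers the inverse correlation matrix", {
  set.seed(2)
  x <- matrix(rnorm(2000 * 4), 2000, 4)
  S <- cor(x)
  fit <- glasso_precision(S, 0)
  expect_lt(max(abs(fit$omega - solve(S))), 1e-10)
})

test_that("small penalties approach the unpenalised inverse", {
  set.seed(9)
  om <- make_default_specs(K = 1, p = 5, sparsity = 0.4, seed = 5,
                           n_total = 10)[[1]]$precision
  S <- cov2cor(solve(om) + diag(5) * 0)        # population correlation
  fit <- glasso_precision(S, 1e-6)
  expect_lt(max(abs(fit$omega - solve(S))), 1e-3)
})

test_that("edges enter as the penalty relaxes from saturation", {
  set.seed(3)
  om <- make_default_specs(K = 1, p = 8, sparsity = 0.3, seed = 7,
                           n_total = 10)[[1]]$precision
  x <- rmvn_precision(1500, om)
  est <- glasso_fit(npn_transform(x))
  kept <- which(!is.na(est$path_edges))
  # saturating penalty gives the empty graph; edge counts then grow through
  # the sparse regime. Exact nestedness over the whole path is NOT a lasso
  # guarantee (edges can drop out again near lambda -> 0; verified against an
  # independent solver), so only the entry regime is asserted.
  expect_equal(est$path_edges[kept[1]], 0L)
  peak <- which.max(est$path_edges[kept])
  expect_true(all(diff(est$path_edges[kept[1:peak]]) >= 0))
  expect_gte(est$path_edges[kept[peak]], sum(abs(om[upper.tri(om)]) > 1e-10))
  expect_equal(est$selection_method, "ebic")
  expect_true(est$lambda %in% est$lambda_path)
})

test_that("partial correlations follow the precision formula", {
  expect_equal(precision_to_pcor(diag(c(2, 3, 4)))$pcor, matrix(0, 3, 3),
               ignore_attr = TRUE)
  om <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_pcor(om)$pcor[1, 2], 0.5)
  expect_error(precision_to_pcor(matrix(c(-1, 0, 0, 1), 2)), "positive")
})

test_that("pcor matches the residual-correlation definition", {
  set.seed(4)
  for (rep in 1:3) {
    om <- make_default_specs(K = 1, p = 3, sparsity = 0.6, seed = rep,
                             n_total = 10)[[1]]$precision
    x <- rmvn_precision(4000, om)
    omega_hat <- solve(cor(x))
    net <- precision_to_pcor(omega_hat)
    for (j in 1:2) for (k in (j + 1):3)
      expect_equal(net$pcor[j, k], residual_pcor(x, j, k), tolerance = 1e-6)
  }
})

test_that("pcor matrices are symmetric, bounded, zero-diagonal", {
  set.seed(5)
  om <- make_default_specs(K = 1, p = 7, sparsity = 0.4, seed = 2,
                           n_total = 10)[[1]]$precision
  x <- rmvn_precision(800, om)
  net <- precision_to_pcor(glasso_fit(npn_transform(x)))
  expect_equal(net$pcor, t(net$pcor))
  expect_true(all(abs(net$pcor) <= 1))
  expect_equal(unname(diag(net$pcor)), rep(0, 7))
})

test_that("EBIC selection recovers a known sparse support", {
  set.seed(6)
  om <- make_default_specs(K = 1, p = 10, sparsity = 0.3, seed = 42,
                           n_total = 10)[[1]]$precision
  x <- rmvn_precision(5000, om)
  est <- glasso_fit(npn_transform(x))
  expect_gte(edge_f1(om, est$omega), 0.8)
})

test_that("fixed selection honours the requested penalty", {
  set.seed(7)
  x <- matrix(rnorm(500 * 4), 500, 4)
  est <- glasso_fit(npn_transform(x), lambda_path = 0.2, selection = "fixed")
  expect_equal(est$lambda, 0.2)
  expect_true(all(is.na(est$ebic)))
})

test_that("monotone deformation of raw data leaves the network unchanged", {
  set.seed(8)
  specs <- make_default_specs(K = 1, p = 5, sparsity = 0.4, seed = 3,
                              n_total = 400)
  sim <- simulate_responses(specs, seed = 9)
  a <- fit_cluster_network(sim$responses, cluster_id = 1)
  b <- fit_cluster_network(exp(sim$responses / 2), cluster_id = 1)
  expect_equal(a$pcor, b$pcor, tolerance = 1e-10)
})

test_that("a constant item keeps its node but loses all edges", {
  set.seed(10)
  x <- cbind(matrix(sample(1:5, 300, TRUE), 100, 3), rep(2L, 100))
  colnames(x) <- paste0("item_", 1:4)
  net <- fit_cluster_network(x, cluster_id = 1)
  expect_equal(net$constant_items, 4L)
  expect_true(all(net$pcor[4, ] == 0) && all(net$pcor[, 4] == 0))
  expect_equal(nrow(net$pcor), 4)
})
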