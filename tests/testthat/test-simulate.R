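test_that("default specs satisfy their construction contract", {
  one <- make_default_specs(K = 1, p = 2, seed = 3, n_total = 10)
  expect_length(one, 1)
  expect_equal(dim(one[[1]]$precision), c(2, 2))
  ev <- eigen(one[[1]]$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)

  specs <- make_default_specs(K = 5, p = 10, sparsity = 0.3, seed = 1)
  expect_length(specs, 5)
  sums <- vapply(specs, function(s) sum(s$mean_shift), 0)
  expect_true(all(diff(sums) > 0))
  # distinct sparsity patterns
  patterns <- lapply(specs, function(s) abs(s$precision) > 1e-10)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(identical(patterns[[i]], patterns[[j]]))
  # thresholds strictly increasing per item
  for (s in specs)
    expect_true(all(apply(s$thresholds, 1, diff) > 0))
  # latent scale is standardised: implied covariance has unit diagonal
  for (s in specs)
    expect_equal(diag(solve(s$precision)), rep(1, 10), tolerance = 1e-10)
})

test_that("specs are deterministic under a fixed seed", {
  a <- make_default_specs(K = 4, p = 8, sparsity = 0.25, seed = 11)
  b <- make_default_specs(K = 4, p = 8, sparsity = 0.25, seed = 11)
  expect_identical(a, b)
  c <- make_default_specs(K = 4, p = 8, sparsity = 0.25, seed = 12)
  expect_false(identical(a, c))
})

test_that("spec validation rejects malformed inputs", {
  expect_error(new_cluster_spec(c(0, 0), matrix(c(1, 2, 0, 1), 2), 5,
                                matrix(0.5, 2, 1)), "symmetric")
  expect_error(new_cluster_spec(c(0, 0), matrix(c(1, 2, 2, 1), 2), 5,
                                matrix(0.5, 2, 1)), "positive definite")
  expect_error(new_cluster_spec(c(0, 0), diag(2), 5,
                                matrix(c(1, 0.5, 0.5, 1), 2, 2)), "increasing")
})

test_that("simulation bookkeeping: sizes, labels, value range, shuffling", {
  specs <- list(
    new_cluster_spec(rep(0, 3), diag(3), 3, matrix(rep(c(-1, 0, 1), each = 3), 3)),
    new_cluster_spec(rep(1, 3), diag(3), 4, matrix(rep(c(-1, 0, 1), each = 3), 3)))
  sim <- simulate_responses(specs, seed = 5)
  expect_equal(nrow(sim$responses), 7)
  expect_equal(as.vector(table(sim$true_labels)), c(3, 4))
  expect_true(all(sim$responses %in% 1:4))
  expect_equal(colnames(sim$responses), paste0("item_", 1:3))
})

test_that("threshold saturation pins every response at 1", {
  spec <- new_cluster_spec(rep(0, 4), diag(4), 50,
                           matrix(rep(c(11, 12, 13, 14), each = 4), 4))
  sim <- simulate_responses(list(spec), seed = 2)
  expect_true(all(sim$responses == 1L))
})

test_that("category frequencies match threshold-implied Gaussian orthants", {
  thr <- matrix(rep(qnorm(c(0.2, 0.4, 0.6, 0.8)), each = 4), 4)
  spec <- new_cluster_spec(rep(0, 4), diag(4), 50000, thr)
  sim <- simulate_responses(list(spec), seed = 99)
  freq <- prop.table(table(factor(sim$responses, levels = 1:5)))
  expect_true(all(abs(as.numeric(freq) - 0.2) < 0.01))
})

test_that("latent correlations match the inverse-precision correlations", {
  specs <- make_default_specs(K = 1, p = 6, sparsity = 0.4, seed = 8,
                              sizes = 20000)
  sim <- simulate_responses(specs, seed = 13)
  target <- cov2cor(solve(specs[[1]]$precision))
  emp <- cor(sim$latents)
  expect_lt(max(abs(emp - target)), 0.05)
})

test_that("identical seed gives bit-identical responses and labels", {
  specs <- make_default_specs(K = 3, p = 5, seed = 4, n_total = 200)
  a <- simulate_responses(specs, seed = 21)
  b <- simulate_responses(specs, seed = 21)
  expect_identical(a$responses, b$responses)
  expect_identical(a$true_labels, b$true_labels)
  expect_false(identical(a$responses, simulate_responses(specs, seed = 22)$responses))
})

test_that("singular precision is reported with the offending cluster", {
  spec <- new_cluster_spec(rep(0, 3), diag(3), 5,
                           matrix(rep(c(-1, 0, 1), each = 3), 3))
  spec$precision <- matrix(1, 3, 3)      # rank-1: chol must fail
  expect_error(simulate_responses(list(spec), seed = 1), "cluster 1")
})

test_that("floor-heavy defaults pile the lowest cluster at response 1", {
  sim <- simulate_responses(make_default_specs(K = 5, p = 10, seed = 2), seed = 7)
  low <- sim$responses[sim$true_labels == 1, ]
  expect_gt(mean(low == 1L), 0.9)
})

test_that("simulation round-trips through CSV", {
  sim <- simulate_responses(make_default_specs(K = 2, p = 4, seed = 6,
                                               n_total = 60), seed = 3)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_responses(file.path(dir, "responses.csv"))
  expect_identical(unname(back), unname(sim$responses))
  expect_identical(colnames(back), colnames(sim$responses))
})
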