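test_that("strength sums absolute incident weights", {
  w <- matrix(0, 3, 3)
  expect_equal(unname(node_strength(as_network(w))), c(0, 0, 0))
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- -0.3
  expect_equal(unname(node_strength(as_network(w))), c(0.8, 0.5, 0.3))
  set.seed(1)
  r <- random_weight_matrix(8)
  expect_equal(unname(node_strength(as_network(r))), unname(rowSums(abs(r))))
})

test_that("a two-link chain has the textbook path metrics", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  sp <- shortest_path_metrics(as_network(w))
  expect_equal(unname(sp$closeness), c(1 / 3, 1 / 2, 1 / 3))
  expect_equal(unname(sp$betweenness), c(0, 1, 0))
})

test_that("complete equal-weight networks have zero betweenness", {
  w <- matrix(0.4, 4, 4); diag(w) <- 0
  sp <- shortest_path_metrics(as_network(w))
  expect_equal(unname(sp$betweenness), rep(0, 4))
  expect_equal(unname(sp$closeness), rep(1 / 2.5, 4))
})

test_that("isolated nodes get zero closeness and betweenness", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.8
  sp <- shortest_path_metrics(as_network(w))
  expect_equal(unname(sp$closeness[3]), 0)
  expect_equal(unname(sp$betweenness[3]), 0)
  expect_gt(sp$closeness[1], 0)
})

test_that("path metrics agree with exhaustive enumeration on small graphs", {
  set.seed(2)
  for (rep in 1:30) {
    p <- sample(3:6, 1)
    w <- random_weight_matrix(p, edge_prob = 0.6)
    sp <- shortest_path_metrics(as_network(w))
    oracle <- path_metrics_oracle(w)
    expect_equal(unname(sp$closeness), oracle$closeness, tolerance = 1e-10)
    expect_equal(unname(sp$betweenness), oracle$betweenness, tolerance = 1e-8)
  }
})

test_that("density and connectivity follow their definitions", {
  w <- matrix(0, 3, 3)
  gc0 <- global_connectivity(as_network(w))
  expect_equal(gc0$density, 0)
  expect_equal(gc0$connectivity, 0)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- -0.3
  gc <- global_connectivity(as_network(w))
  expect_equal(gc$density, 0.8 / 3)
  expect_equal(gc$connectivity, 2 / 3)
  wf <- matrix(0.25, 5, 5); diag(wf) <- 0
  gcf <- global_connectivity(as_network(wf))
  expect_equal(gcf$density, 0.25)
  expect_equal(gcf$connectivity, 1)
})

test_that("edge-weight scaling acts as expected on every metric", {
  set.seed(3)
  w <- random_weight_matrix(6, edge_prob = 0.5)
  c <- 3.7
  a <- as_network(w); b <- as_network(c * w)
  expect_equal(node_strength(b), c * node_strength(a))
  spa <- shortest_path_metrics(a); spb <- shortest_path_metrics(b)
  expect_equal(spb$closeness, c * spa$closeness)
  expect_equal(spb$betweenness, spa$betweenness)
  ga <- global_connectivity(a); gb <- global_connectivity(b)
  expect_equal(gb$density, c * ga$density)
  expect_equal(gb$connectivity, ga$connectivity)
})

test_that("KS comparisons behave at the degenerate extremes", {
  tab <- data.frame(cluster = rep(1:2, each = 10), node = rep(letters[1:10], 2),
                    strength = c(1:10, 1:10) / 10,
                    closeness = c(1:10, 101:110) / 10,
                    betweenness = rep(0, 20))
  same <- ks_compare(tab, "strength")
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  apart <- ks_compare(tab, "closeness")
  expect_equal(apart$D, 1)
  expect_equal(attr(apart, "n_tests"), 1L)
})

test_that("KS D is invariant to common increasing transforms", {
  set.seed(4)
  tab <- data.frame(cluster = rep(1:3, each = 10),
                    strength = rgamma(30, 2), closeness = 0, betweenness = 0)
  tab2 <- tab; tab2$strength <- log(tab$strength + 1)
  expect_equal(ks_compare(tab, "strength")$D, ks_compare(tab2, "strength")$D)
  expect_equal(nrow(ks_compare(tab, "strength")), 3)   # all unordered pairs
})

test_that("KS comparison rejects undersized inputs", {
  tab <- data.frame(cluster = c(1, 2, 2), strength = c(1, 2, 3),
                    closeness = 0, betweenness = 0)
  expect_error(ks_compare(tab, "strength"), "at least two centrality values")
  expect_error(ks_compare(tab[tab$cluster == 1, , drop = FALSE], "strength"),
               "at least two clusters")
})

test_that("centrality tables stack clusters with brute-force-checked strengths", {
  set.seed(5)
  nets <- lapply(1:3, function(i) as_network(random_weight_matrix(5), i))
  tab <- centrality_table(nets)
  expect_equal(nrow(tab), 15)
  expect_equal(unique(tab$cluster), 1:3)
  for (i in 1:3)
    expect_equal(tab$strength[tab$cluster == i],
                 unname(rowSums(abs(nets[[i]]$pcor))))
})
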