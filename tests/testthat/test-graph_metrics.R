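k_n <- function(n) matrix(1, n, n) - diag(n)
path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in 1:(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

test_that("shortest paths and path length match closed forms and enumeration", {
  expect_true(all(shortest_path_lengths(k_n(4))[upper.tri(diag(4))] == 1))
  expect_equal(shortest_path_lengths(path_graph(3))[1, 3], 2)
  expect_equal(characteristic_path_length(k_n(6)), 1)
  expect_equal(characteristic_path_length(path_graph(4)), 10 / 6)

  set.seed(2)
  for (i in 1:5) {
    a <- random_connected_graph(7, 0.4, weighted = TRUE)
    expect_equal(shortest_path_lengths(a), oracle_apsp(a), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # second independent algorithm on a larger small-world graph
  set.seed(3)
  g <- igraph::sample_smallworld(1, 32, 3, 0.1)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  o <- oracle_sp_nodes(a)
  expect_equal(characteristic_path_length(a),
               mean(o$d[upper.tri(o$d)]), tolerance = 1e-10)
})

test_that("clustering matches triangle enumeration; weighted reduces to binary", {
  tri <- k_n(3)
  expect_equal(clustering_coefficient(tri), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clustering_coefficient(star), 0)
  k4m <- k_n(4); k4m[3, 4] <- k4m[4, 3] <- 0
  expect_equal(clustering_coefficient(k4m), 5 / 6)

  set.seed(6)
  for (i in 1:5) {
    a <- random_connected_graph(8, 0.45, weighted = TRUE)
    expect_equal(clustering_coefficient(a), oracle_clustering(a),
                 tolerance = 1e-12)
    b <- (a > 0) + 0
    expect_equal(clustering_coefficient(b), oracle_clustering(b),
                 tolerance = 1e-12)
  }
})

test_that("efficiencies match their definitions on known and random graphs", {
  expect_equal(global_efficiency(k_n(5)), 1)
  expect_equal(global_efficiency(path_graph(3)), 5 / 6)
  iso <- rbind(cbind(k_n(3), 0), 0)  # triangle plus isolated node
  expect_equal(global_efficiency(iso), (3 * 1) / 6)

  expect_equal(local_efficiency(k_n(4)), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(local_efficiency(star), 0)
  set.seed(8)
  for (i in 1:4) {
    a <- random_connected_graph(8, 0.45)
    expect_equal(global_efficiency(a), oracle_global_eff(a), tolerance = 1e-10)
    expect_equal(local_efficiency(a), oracle_local_eff(a), tolerance = 1e-10)
  }
})

test_that("modularity finds optimal partitions on structured graphs", {
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- k_n(3); two_tri[4:6, 4:6] <- k_n(3)
  mod <- modularity_partition(two_tri, seed = 1, n_restarts = 10)
  expect_equal(mod$Q, 0.5)
  expect_equal(mod$Q, oracle_best_q(two_tri), tolerance = 1e-12)
  expect_equal(length(unique(mod$membership[1:3])), 1)
  expect_equal(length(unique(mod$membership[4:6])), 1)
  expect_false(mod$membership[1] == mod$membership[4])
  # returned Q never falls below the trivial single-module baseline
  expect_gte(mod$Q, 0)

  # complete graph: no community structure
  expect_lt(abs(modularity_partition(k_n(8), 1, 10)$Q), 1e-12)

  # planted two-block structure is recovered
  set.seed(13)
  n <- 32
  blocks <- rep(1:2, each = 16)
  a <- matrix(0, n, n)
  up <- which(upper.tri(a), arr.ind = TRUE)
  p <- ifelse(blocks[up[, 1]] == blocks[up[, 2]], 0.9, 0.05)
  a[upper.tri(a)] <- as.numeric(runif(nrow(up)) < p)
  a <- a + t(a)
  memb <- modularity_partition(a, seed = 2, n_restarts = 20)$membership
  expect_equal(length(unique(memb)), 2)
  expect_true(all(memb[1:16] == memb[1]) && all(memb[17:32] == memb[17]))

  expect_error(modularity_partition(matrix(0, 4, 4)), "empty")
})

test_that("rewired nulls preserve degrees and weights but destroy lattice clustering", {
  set.seed(14)
  g <- igraph::sample_smallworld(1, 32, 3, 0)   # pure lattice
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  w <- a
  w[upper.tri(w)] <- w[upper.tri(w)] * runif(sum(upper.tri(w)), 0.2, 1)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  nulls <- random_reference(w, n_random = 20, seed = 5)
  for (nl in nulls) {
    expect_identical(node_degree(nl), node_degree(w))
    expect_equal(sort(nl[upper.tri(nl)][nl[upper.tri(nl)] > 0]),
                 sort(w[upper.tri(w)][w[upper.tri(w)] > 0]))
  }
  c_lattice <- clustering_coefficient((w > 0) + 0)
  c_null <- mean(sapply(nulls, function(nl) clustering_coefficient((nl > 0) + 0)))
  expect_lt(c_null, c_lattice / 2)
})

test_that("normalization yields sigma = gamma/lambda and detects small worlds", {
  set.seed(15)
  # Erdos-Renyi graph is statistically similar to its rewired nulls
  a <- random_connected_graph(32, 0.25)
  nm <- normalized_metrics(a, random_reference(a, 20, seed = 2))
  expect_equal(nm$sigma, nm$gamma / nm$lambda, tolerance = 1e-12)
  expect_lt(abs(nm$lambda - 1), 0.1)
  expect_lt(abs(nm$gamma - 1), 0.35)

  # small-world graph: sigma > 1
  g <- igraph::sample_smallworld(1, 32, 3, 0.1)
  ws <- as.matrix(igraph::as_adjacency_matrix(g))
  nm_ws <- normalized_metrics(ws, random_reference(ws, 20, seed = 3))
  expect_gt(nm_ws$sigma, 1)

  # metrics invariant under node relabeling
  perm <- sample(32)
  nmp <- normalized_metrics(ws[perm, perm],
                            random_reference(ws[perm, perm], 20, seed = 3))
  expect_equal(nmp$L, nm_ws$L, tolerance = 1e-12)
  expect_equal(nmp$C, nm_ws$C, tolerance = 1e-12)
})
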