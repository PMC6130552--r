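mk_conn <- function(v, n) connectome(fadconn:::sym_from_ut(v, n))

test_that("proportional thresholding keeps the strongest edges deterministically", {
  c4 <- mk_conn(c(0.9, 0.8, 0.5, 0.2, 0.1, 0.05), 4)
  # d = 1 keeps everything
  expect_equal(threshold_at_density(c4, 1)$matrix, c4$matrix)
  # d = 0.5 keeps the top 3
  th <- threshold_at_density(c4, 0.5)
  expect_setequal(th$matrix[upper.tri(th$matrix)][th$matrix[upper.tri(th$matrix)] > 0],
                  c(0.9, 0.8, 0.5))
  # binarize flag
  thb <- threshold_at_density(c4, 0.5, binarize = TRUE)
  expect_setequal(unique(as.vector(thb$matrix)), c(0, 1))
  expect_false(thb$weighted)

  # tie at the cut: lexicographically first (i, j) wins
  # upper triangle of a 3-node graph in column-major order: (1,2), (1,3), (2,3)
  c3 <- mk_conn(c(0.5, 0.5, 0.2), 3)
  t1 <- threshold_at_density(c3, 1 / 3)
  expect_equal(t1$matrix[1, 2], 0.5)
  expect_equal(t1$matrix[1, 3], 0)
  expect_error(threshold_at_density(c4, 0.01), "single edge")
})

test_that("thresholded edge sets are nested across densities", {
  set.seed(21)
  for (rep in 1:5) {
    v <- runif(45) * (runif(45) < 0.8)
    conn <- mk_conn(v, 10)
    prev <- NULL
    for (d in c(0.1, 0.25, 0.4, 0.7, 1)) {
      cur <- threshold_at_density(conn, d)$matrix > 0
      if (!is.null(prev)) expect_true(all(cur[prev]))
      prev <- cur
    }
  }
})

test_that("minimum connection density matches an exhaustive connectivity scan", {
  # star topology: connected exactly when all 31 hub edges are present
  star <- matrix(0, 32, 32)
  star[1, 2:32] <- star[2:32, 1] <- runif(31, 0.5, 1)
  expect_equal(minimum_connection_density(list(connectome(star))), 0.07)

  # two cliques never connect
  blocks <- matrix(0, 8, 8)
  blocks[1:4, 1:4] <- 0.5; blocks[5:8, 5:8] <- 0.5
  diag(blocks) <- 0
  expect_error(minimum_connection_density(list(connectome(blocks))),
               "disconnected")

  # random cohort equals brute-force scan over the grid
  set.seed(33)
  conns <- lapply(1:4, function(i)
    connectome(random_connected_graph(8, 0.5, weighted = TRUE)))
  got <- minimum_connection_density(conns, step = 0.01)
  grid <- density_grid(0.01)
  brute <- grid[which(sapply(grid, function(d) {
    all(sapply(conns, function(cn) {
      m <- try(threshold_at_density(cn, d)$matrix, silent = TRUE)
      if (inherits(m, "try-error")) return(FALSE)
      oracle_connected(m)
    }))
  }))[1]]
  expect_equal(got, brute)
})

test_that("the small-world window is capped and sigma-bounded", {
  grid <- density_grid(0.01, 0.6)
  grid <- grid[grid >= 0.24]
  sig <- matrix(1.5, 2, length(grid))
  w <- small_world_density_range(sig, grid, d_min = 0.24, d_max = 0.5)
  expect_equal(c(w$d_lo, w$d_hi), c(0.24, 0.5))

  # sigma drops below 1 at 0.40: window ends one step before
  sig2 <- matrix(rep(ifelse(grid < 0.40, 1.4, 0.9), each = 2), 2)
  w2 <- small_world_density_range(sig2, grid, d_min = 0.24)
  expect_equal(w2$d_hi, 0.39)

  expect_error(small_world_density_range(matrix(0.8, 2, length(grid)),
                                         grid, 0.24), "no small-world")

  # "all subjects" rule is stricter than the group mean
  sig3 <- rbind(rep(1.6, length(grid)), ifelse(grid < 0.3, 1.2, 0.7))
  w_mean <- small_world_density_range(sig3, grid, 0.24, rule = "mean")
  w_all <- small_world_density_range(sig3, grid, 0.24, rule = "all")
  expect_lte(w_all$d_hi, w_mean$d_hi)
})

test_that("crossover detection finds the first sign change of the mean curves", {
  grid <- c(0.24, 0.30, 0.34, 0.40)
  expect_equal(find_crossover(c(2, 2, 1, 1), c(1, 1, 2, 2), grid), 0.34)
  expect_null(find_crossover(c(1, 2, 3, 4), c(1, 2, 3, 4), grid))
  expect_null(find_crossover(c(2, 3, 4, 5), c(1, 2, 3, 4), grid))
})

test_that("window AUC is the trapezoidal integral and is additive", {
  grid <- density_grid(0.01)
  vals <- rep(2, length(grid))
  expect_equal(auc_over_window(vals, grid, c(0.3, 0.5)), 0.4)
  # linear curve integrates to the exact quadratic area
  lin <- grid
  expect_equal(auc_over_window(lin, grid, c(0.01, 1)), (1 - 0.01^2) / 2)

  set.seed(4)
  vals2 <- runif(length(grid))
  a <- auc_over_window(vals2, grid, c(0.1, 0.3))
  b <- auc_over_window(vals2, grid, c(0.3, 0.8))
  ab <- auc_over_window(vals2, grid, c(0.1, 0.8))
  expect_equal(a + b, ab, tolerance = 1e-12)

  # matches an independent cumulative-sum quadrature on the grid points
  idx <- which(grid >= 0.1 & grid <= 0.8)
  alt <- sum((vals2[idx][-1] + vals2[idx][-length(idx)]) / 2 * diff(grid[idx]))
  expect_equal(ab, alt, tolerance = 1e-12)

  expect_error(auc_over_window(vals2, grid, c(0.105, 0.3)), "grid")
})
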