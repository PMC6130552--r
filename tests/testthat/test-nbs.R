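sym_noise <- function(n, mu = 0, sd = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- pmax(rnorm(n * (n - 1) / 2, mu, sd), 0)
  m + t(m)
}

test_that("edge-wise contrast is zero for identical groups and flags the planted edge", {
  set.seed(71)
  nets <- lapply(1:4, function(i) sym_noise(10, 1, 0.2))
  tm <- suppressWarnings(edgewise_contrast(nets, nets))
  expect_true(all(tm == 0))

  a <- lapply(1:6, function(i) sym_noise(10, 1, 0.2))
  b <- lapply(1:6, function(i) sym_noise(10, 1, 0.2))
  a <- lapply(a, function(m) { m[2, 7] <- m[7, 2] <- m[2, 7] + 1.5; m })
  tab <- edgewise_contrast(a, b)
  expect_equal(which.max(abs(tab[upper.tri(tab)])),
               which(fadconn:::ut_pairs(10)[, 1] == 2 &
                     fadconn:::ut_pairs(10)[, 2] == 7))
  # swapping groups negates every t
  expect_equal(edgewise_contrast(b, a), -tab, tolerance = 1e-12)
})

test_that("NBS detects a planted connected component with FWE control", {
  set.seed(72)
  n <- 32
  comp_edges <- cbind(c(1, 2, 3, 4, 5, 1), c(2, 3, 4, 5, 6, 3))
  a <- lapply(1:8, function(i) {
    m <- sym_noise(n, 1, 0.3)
    m[comp_edges] <- m[comp_edges] + 1.6
    m[comp_edges[, 2:1]] <- m[comp_edges]
    m
  })
  b <- lapply(1:8, function(i) sym_noise(n, 1, 0.3))
  res <- nbs_test(a, b, threshold = 3, mode = "extent", n_perm = 500, seed = 4)
  expect_gt(length(res$components), 0)
  big <- which.max(res$scores)
  expect_lt(res$p_fwe[big], 0.05)
  # the detected component covers the planted nodes
  found <- unique(c(res$components[[big]]$region_a,
                    res$components[[big]]$region_b))
  expect_gte(length(intersect(found, paste0("R", 1:6))), 4)

  # component scores are invariant to node relabeling
  perm <- sample(n)
  ap <- lapply(a, function(m) m[perm, perm])
  bp <- lapply(b, function(m) m[perm, perm])
  resp <- nbs_test(ap, bp, threshold = 3, mode = "extent", n_perm = 50, seed = 4)
  expect_equal(sort(resp$scores), sort(res$scores))
})

test_that("intensity mode is more sensitive than extent to a single focal edge", {
  set.seed(73)
  n <- 16
  a <- lapply(1:8, function(i) {
    m <- sym_noise(n, 1, 0.25)
    m[3, 9] <- m[9, 3] <- m[3, 9] + 3   # one very strong focal effect
    m
  })
  b <- lapply(1:8, function(i) sym_noise(n, 1, 0.25))
  ext <- nbs_test(a, b, threshold = 3, mode = "extent", n_perm = 500, seed = 9)
  int <- nbs_test(a, b, threshold = 3, mode = "intensity", n_perm = 500, seed = 9)
  focal_p <- function(res) {
    hit <- vapply(res$components, function(cc)
      any(cc$region_a == "R3" & cc$region_b == "R9"), TRUE)
    res$p_fwe[which(hit)[1]]
  }
  expect_lt(focal_p(int), focal_p(ext))
})

test_that("edge-wise FDR applies the Benjamini-Hochberg step-up rule", {
  set.seed(74)
  # no signal anywhere: empty discovery set
  a <- lapply(1:8, function(i) sym_noise(12, 1, 0.3))
  b <- lapply(1:8, function(i) sym_noise(12, 1, 0.3))
  expect_equal(nrow(fdr_edges(a, b)), 0)

  # one overwhelming edge among all pairs survives alone
  a2 <- lapply(a, function(m) { m[2, 5] <- m[5, 2] <- m[2, 5] + 50; m })
  hits <- fdr_edges(a2, b)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$region_a, hits$region_b), c("R2", "R5"))
  # matches p.adjust on the same p-values
  expect_lt(hits$p_adj, 0.05)
})
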