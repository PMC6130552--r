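test_that("search information matches hand computations and path enumeration", {
  # single edge: the walker has no choice
  two <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(search_information(two)[1, 2], 0)

  # path A-B-C with unit weights: one binary choice at B
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- 1; p3[2, 3] <- p3[3, 2] <- 1
  si3 <- search_information(p3)
  expect_equal(si3[1, 3], 1)
  expect_equal(si3[3, 1], 1)
  expect_equal(si3[1, 2], 0)

  set.seed(61)
  for (i in 1:5) {
    a <- random_connected_graph(8, 0.4, weighted = TRUE)
    si <- search_information(a)
    o <- oracle_sp_nodes(a)
    for (s in 1:8) for (t in 1:8) {
      if (s == t) next
      expect_equal(si[s, t], oracle_si_along(a, o$path(s, t)),
                   tolerance = 1e-10)
    }
  }
})

test_that("path transitivity averages matching along the path and is symmetric", {
  # bridge with private pendants: endpoints share no neighbors
  g <- matrix(0, 4, 4)
  g[1, 2] <- g[2, 1] <- 1   # bridge s-t
  g[1, 3] <- g[3, 1] <- 1   # pendant of s
  g[2, 4] <- g[4, 2] <- 1   # pendant of t
  expect_equal(path_transitivity(g)[1, 2], 0)

  # complete graph: direct paths, PT equals the matching index itself
  k5 <- matrix(1, 5, 5) - diag(5)
  pt5 <- path_transitivity(k5)
  m5 <- oracle_matching(k5)
  expect_equal(pt5[upper.tri(pt5)], m5[upper.tri(m5)], tolerance = 1e-12)

  set.seed(62)
  a <- random_connected_graph(8, 0.45, weighted = TRUE)
  pt <- path_transitivity(a)
  expect_equal(pt, t(pt), tolerance = 1e-12)
  expect_true(all(pt[is.finite(pt)] >= 0 & pt[is.finite(pt)] <= 1))
})

test_that("matching index and neighborhood overlap match set computations", {
  # two nodes with identical neighborhoods
  g <- matrix(0, 4, 4)
  g[1, 3] <- g[3, 1] <- 1; g[1, 4] <- g[4, 1] <- 1
  g[2, 3] <- g[3, 2] <- 1; g[2, 4] <- g[4, 2] <- 1
  expect_equal(matching_index(g)[1, 2], 1)
  expect_equal(neighborhood_overlap(g)[1, 2], 1)

  # disjoint neighborhoods
  h <- matrix(0, 6, 6)
  h[1, 3] <- h[3, 1] <- 1; h[1, 4] <- h[4, 1] <- 1
  h[2, 5] <- h[5, 2] <- 1; h[2, 6] <- h[6, 2] <- 1
  expect_equal(matching_index(h)[1, 2], 0)
  expect_equal(neighborhood_overlap(h)[1, 2], 0)

  set.seed(63)
  a <- random_connected_graph(5, 0.6, weighted = TRUE)
  expect_equal(matching_index(a), oracle_matching(a), tolerance = 1e-12,
               ignore_attr = TRUE)
  bin <- (a > 0) + 0
  no <- neighborhood_overlap(a)
  for (i in 1:4) for (j in (i + 1):5) {
    k <- setdiff(1:5, c(i, j))
    inter <- sum(bin[i, k] & bin[j, k]); uni <- sum(bin[i, k] | bin[j, k])
    expect_equal(no[i, j], if (uni > 0) inter / uni else 0)
  }
})

test_that("mean first passage time solves the chain and z-scores per column", {
  two <- matrix(c(0, 1, 1, 0), 2)
  raw <- mean_first_passage_time(two, zscore = FALSE)
  expect_equal(raw[1, 2], 1)
  expect_equal(raw[2, 1], 1)
  expect_equal(mean_first_passage_time(two)[1, 2], 0)  # degenerate column

  set.seed(64)
  a <- random_connected_graph(8, 0.45, weighted = TRUE)
  raw8 <- mean_first_passage_time(a, zscore = FALSE)
  expect_equal(raw8, oracle_mfpt(a), tolerance = 1e-8, ignore_attr = TRUE)

  # one entry double-checked by direct walk simulation
  P <- a / rowSums(a)
  sim <- replicate(20000, {
    pos <- 1L; steps <- 0L
    while (pos != 5L) { pos <- sample.int(8, 1, prob = P[pos, ]); steps <- steps + 1L }
    steps
  })
  expect_lt(abs(mean(sim) - raw8[1, 5]) / raw8[1, 5], 0.05)

  z <- mean_first_passage_time(a)
  for (j in 1:8) {
    expect_equal(mean(z[-j, j]), 0, tolerance = 1e-12)
    expect_equal(sd(z[-j, j]), 1, tolerance = 1e-12)
  }
})

test_that("coupling regression is exact on constructed data and nested in fit", {
  set.seed(65)
  sc <- random_connected_graph(12, 0.5, weighted = TRUE)
  meas <- comm_measures(sc, "default")
  # FC built as an exact linear combination of the default measures
  fc_lin <- 0.5 + 0.2 * meas$SPL - 0.1 * meas$SI
  diag(fc_lin) <- 0
  res <- predict_fc(sc, fc_lin, "default")
  expect_equal(res$r, 1, tolerance = 1e-8)

  # independent noise: no coupling
  noise <- matrix(0, 12, 12)
  noise[upper.tri(noise)] <- abs(rnorm(66))
  noise <- noise + t(noise)
  expect_lt(abs(predict_fc(sc, noise, "default")$r), 0.35)

  # the all-measures model can never fit worse in sample
  coh <- gen_cohort(synth_config(per_group = 2), seed = 8)
  for (id in coh$subjects$id) {
    r_def <- predict_fc(coh$sc[[id]], coh$fc[[id]], "default")$r
    r_all <- predict_fc(coh$sc[[id]], coh$fc[[id]], "all")$r
    expect_gte(r_all, r_def - 1e-10)
  }

  # shifting all observed FC leaves the coupling correlation unchanged
  fc1 <- coh$fc[[1]]$matrix
  r1 <- predict_fc(coh$sc[[1]], fc1, "default")$r
  r2 <- predict_fc(coh$sc[[1]], fc1 + 0.25 - diag(0.25, 32), "default")$r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("group comparison of coupling uses Fisher-z pooled t", {
  ra <- c(0.5, 0.52, 0.48); rb <- c(0.5, 0.52, 0.48)
  eq <- compare_coupling(ra, rb)
  expect_lt(abs(eq$t), 1e-10)
  ct <- compare_coupling(c(0.2, 0.25, 0.22), c(0.6, 0.62, 0.65))
  manual <- two_sample_t(atanh(c(0.2, 0.25, 0.22)), atanh(c(0.6, 0.62, 0.65)))
  expect_equal(ct$t, manual$t)
  expect_lt(ct$p, 0.01)
})
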