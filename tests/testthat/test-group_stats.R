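test_that("AUC permutation test gives exact p on enumerable designs", {
  grid <- seq(0.2, 0.5, by = 0.05)
  flat <- function(v) t(sapply(v, function(x) rep(x, length(grid))))
  # identical groups: every relabeling ties the observed difference
  same <- flat(c(1, 1, 1, 1))
  res <- auc_permutation_test(same, same, grid, c(0.2, 0.5))
  expect_equal(res$p, 1)
  # complete separation, 4 vs 4: exactly 2 of the 70 assignments are as extreme
  a <- flat(c(10, 11, 12, 13)); b <- flat(c(1, 2, 3, 4))
  res2 <- auc_permutation_test(a, b, grid, c(0.2, 0.5))
  expect_true(res2$exact)
  expect_equal(res2$p, 2 / 70)
  expect_gt(res2$delta, 0)
  # label exchange flips the sign but not the p
  res3 <- auc_permutation_test(b, a, grid, c(0.2, 0.5))
  expect_equal(res3$p, res2$p)
  expect_equal(res3$delta, -res2$delta)
})

test_that("Monte-Carlo permutation p converges to the exact enumeration", {
  set.seed(77)
  grid <- seq(0.1, 0.5, by = 0.1)
  a <- t(sapply(rnorm(4, 1), function(x) rep(x, 5)))
  b <- t(sapply(rnorm(4, 0), function(x) rep(x, 5)))
  exact <- auc_permutation_test(a, b, grid, c(0.1, 0.5), exact = TRUE)$p
  mc <- mean(sapply(1:8, function(s)
    auc_permutation_test(a, b, grid, c(0.1, 0.5), n_perm = 2000,
                         seed = s, exact = FALSE)$p))
  expect_lt(abs(mc - exact), 0.01)
})

test_that("density-covaried group model reproduces the two-model F computation", {
  set.seed(31)
  g <- rep(c(0, 1), each = 4)
  dens <- runif(8, 0.3, 0.6)
  # response orthogonal to group given density: F collapses to ~0
  raw <- rnorm(8)
  y0 <- dens + residuals(lm(raw ~ g + dens))
  expect_lt(glm_group_test(y0, g, dens)$F, 1e-8)

  # perfect group separation with constant density: reported without overflow
  res_inf <- glm_group_test(g, g, rep(0.5, 8))
  expect_true(is.infinite(res_inf$F))
  expect_equal(res_inf$p, 0)

  # random response matches the textbook RSS computation via normal equations
  y <- rnorm(8)
  X_full <- cbind(1, g, dens)
  X_red <- cbind(1, dens)
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  f_manual <- (rss(X_red) - rss(X_full)) / (rss(X_full) / 5)
  res <- glm_group_test(y, g, dens)
  expect_equal(res$F, f_manual, tolerance = 1e-10)
  expect_equal(res$df, 5L)
  expect_equal(res$p, pf(f_manual, 1, 5, lower.tail = FALSE), tolerance = 1e-10)

  expect_error(glm_group_test(y, g, g * 0.1 + 0.2), "collinear")
})

test_that("pooled t test matches its closed form and is antisymmetric", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)  # = -3.674
  expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)
  expect_equal(res$df, 4)

  eq <- two_sample_t(c(1, 2), c(2, 1))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  swap <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)
})

test_that("small-world filter excludes sigma <= 1 strictly and guards groups", {
  sig <- c(a1 = 1.5, a2 = 1.2, b1 = 0.9, b2 = 1.3)
  grp <- c("A", "A", "B", "B")
  expect_silent({
    all_in <- small_world_filter(sig + 1, grp)
  })
  expect_length(all_in$excluded, 0)

  flt <- suppressMessages(small_world_filter(sig, grp))
  expect_equal(flt$excluded, "b1")

  # sigma exactly 1 is not small-world
  sig2 <- c(a1 = 1.5, a2 = 1.2, b1 = 1.0, b2 = 1.3)
  expect_equal(suppressMessages(small_world_filter(sig2, grp))$excluded, "b1")

  sig3 <- c(a1 = 1.5, a2 = 1.2, b1 = 0.9, b2 = 0.8)
  expect_error(small_world_filter(sig3, grp), "eliminated")
})
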