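test_that("complementary cumulative distribution counts tail mass correctly", {
  ccdf <- cumulative_degree_distribution(c(1, 1, 2, 3))
  expect_equal(ccdf$k, c(1, 2, 3))
  expect_equal(ccdf$p, c(1, 0.5, 0.25))
  expect_equal(ccdf$p[1], 1)
  expect_true(all(diff(ccdf$p) <= 0))

  # regular graph: a single step
  ring <- igraph::as_adjacency_matrix(igraph::sample_smallworld(1, 16, 2, 0))
  reg <- cumulative_degree_distribution(as.matrix(ring))
  expect_equal(nrow(reg), 1)
  expect_equal(reg$p, 1)

  star <- matrix(0, 32, 32); star[1, 2:32] <- star[2:32, 1] <- 1
  st <- cumulative_degree_distribution(star)
  expect_equal(st$k, c(1, 31))
  expect_equal(st$p, c(1, 1 / 32))

  expect_error(cumulative_degree_distribution(matrix(0, 4, 4)), "empty")
})

test_that("the discrete MLE recovers a known exponent", {
  set.seed(55)
  x <- rpower_law(5000, alpha = 2.5, xmin = 1, discrete = TRUE)
  fit <- fit_power_law(x, discrete = TRUE)
  expect_gt(fit$alpha, 2.4)
  expect_lt(fit$alpha, 2.6)
  expect_true(fit$xmin >= 1)
  expect_true(fit$ks >= 0 && fit$ks <= 1)

  expect_error(fit_power_law(rep(3, 100)), "identical")
  expect_error(fit_power_law(c(-1, 2, 3)), "positive")
})

test_that("bootstrap goodness of fit rejects misspecified data", {
  set.seed(56)
  # exponential data are not a power law (cutoff held at the support edge;
  # with a free cutoff the fit can always retreat into the far tail)
  x_exp <- rexp(5000, rate = 0.8) + 1
  fit_exp <- fit_power_law(x_exp, discrete = FALSE, xmins = 1)
  gof_exp <- bootstrap_gof(fit_exp, n_boot = 99, seed = 2, xmins = 1)
  expect_lt(gof_exp$p, 0.05)

  # correctly specified data is not rejected
  x_pl <- rpower_law(800, alpha = 2.5, xmin = 1, discrete = FALSE)
  fit_pl <- fit_power_law(x_pl, discrete = FALSE)
  gof_pl <- bootstrap_gof(fit_pl, n_boot = 99, seed = 3)
  expect_gt(gof_pl$p, 0.1)
})

test_that("GOF p-values are approximately uniform under the true model", {
  set.seed(57)
  ps <- sapply(1:40, function(i) {
    x <- rpower_law(300, alpha = 2.5, xmin = 1, discrete = FALSE)
    bootstrap_gof(fit_power_law(x, discrete = FALSE), n_boot = 60,
                  seed = i)$p
  })
  # bootstrap p-values are discrete (n_boot + 1 atoms), so ks.test warns
  # about ties; the uniformity check itself is unaffected
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("truncated power-law fit never loses to its nested pure power law", {
  set.seed(58)
  x <- rpower_law(1500, alpha = 2.2, xmin = 1, discrete = FALSE)
  tf <- fit_truncated_power_law(x, xmin = 1)
  expect_gte(tf$loglik, tf$loglik_pl - 1e-4)
  expect_gt(tf$alpha, 1)
  expect_gt(tf$rate, 0)
})

test_that("group comparison of fits is a two-tailed KS permutation test", {
  # identical fit statistics in both groups: no relabeling can beat the tie
  expect_equal(compare_fit_between_groups(c(0.1, 0.1, 0.1),
                                          c(0.1, 0.1, 0.1))$p, 1)

  set.seed(59)
  # planted difference: one group exponential, the other power law
  fits_a <- lapply(1:4, function(i)
    fit_power_law(rpower_law(600, 2.5, discrete = FALSE), discrete = FALSE))
  fits_b <- lapply(1:4, function(i)
    fit_power_law(rexp(600, 0.5) + 1, discrete = FALSE))
  res <- compare_fit_between_groups(fits_a, fits_b, n_perm = 500, seed = 1)
  expect_lt(res$p, 0.05)
})
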