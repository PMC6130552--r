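## between-group inference ---------------------------------------------------

# permutation test on difference of group means; exhaustive when requested
# or when the label assignments are few enough to enumerate.
perm_diff_test <- function(vals_a, vals_b, n_perm = 2000L, seed = 1L,
                           exact = NULL) {
  na <- length(vals_a); nb <- length(vals_b)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  pooled <- c(vals_a, vals_b)
  obs <- mean(vals_a) - mean(vals_b)
  n_total <- choose(na + nb, na)
  if (is.null(exact)) exact <- n_total <= n_perm
  if (!exact && n_perm < 100)
    warning("fewer than 100 permutations; p is coarse")
  eps <- 1e-12 * (1 + abs(obs))
  if (exact) {
    idx <- utils::combn(na + nb, na)
    null <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
    p <- sum(abs(null) >= abs(obs) - eps) / n_total
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      pick <- sample.int(na + nb, na)
      mean(pooled[pick]) - mean(pooled[-pick])
    }, 0)
    p <- (sum(abs(null) >= abs(obs) - eps) + 1) / (n_perm + 1)
  }
  list(delta = obs, p = p, null = null, n_perm = if (exact) n_total else n_perm,
       exact = exact, seed = seed)
}

#' Windowed-AUC permutation test
#'
#' Summarizes each subject's metric curve by its area under the curve over a
#' density window, then tests the group difference of mean AUCs by label
#' permutation. Subject labels (not individual densities) are shuffled, so
#' within-subject dependence across densities is preserved. The two-tailed p
#' uses the +1/(n+1) finite-sample correction and is never exactly zero;
#' when all label assignments can be enumerated (e.g. 4 vs 4: 70), the exact
#' permutation distribution is used instead.
#'
#' @param curves_a,curves_b subjects x densities metric matrices on a common
#'   grid (one row per subject).
#' @param grid the density grid.
#' @param window a [density_window] or `c(lo, hi)`.
#' @param n_perm Monte-Carlo permutations (default 2000).
#' @param seed RNG seed for the label shuffles.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default enumerates when feasible within `n_perm`.
#' @return list with `delta` (mean AUC A - mean AUC B), `p`, `aucs_a`,
#'   `aucs_b`, `null`, `n_perm`, `exact`, `seed`.
#' @export
auc_permutation_test <- function(curves_a, curves_b, grid, window,
                                 n_perm = 2000L, seed = 1L, exact = NULL) {
  curves_a <- rbind(curves_a); curves_b <- rbind(curves_b)
  aucs_a <- apply(curves_a, 1, auc_over_window, grid = grid, window = window)
  aucs_b <- apply(curves_b, 1, auc_over_window, grid = grid, window = window)
  res <- perm_diff_test(aucs_a, aucs_b, n_perm = n_perm, seed = seed,
                        exact = exact)
  c(res, list(aucs_a = aucs_a, aucs_b = aucs_b))
}

#' Group test on weighted-network metrics with density as covariate
#'
#' Weighted (unthresholded) networks differ in density between subjects, so
#' the group comparison fits the ordinary least squares model
#' `y = b0 + b1*group + b2*density` and tests `b1 = 0` with the two-model F
#' statistic `F = (RSS_reduced - RSS_full) / (RSS_full / (n - 3))`.
#'
#' @param values metric value per subject.
#' @param groups two-level factor (or character) per subject.
#' @param densities each subject's weighted-network density (fraction of
#'   nonzero edges).
#' @return list with `F`, `p`, `coefficients`, `df`.
#' @export
glm_group_test <- function(values, groups, densities) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  n <- length(values)
  stopifnot(length(groups) == n, length(densities) == n)
  df <- n - 3L
  if (df < 1) stop("need more than 3 subjects for the density-covaried model")
  g <- as.numeric(groups) - 1
  if (stats::sd(densities) > 0 &&
      abs(stats::cor(g, densities)) > 1 - 1e-10)
    stop("density is collinear with group; the group effect is not identifiable")
  full <- stats::lm(values ~ g + densities)
  red <- stats::lm(values ~ densities)
  rss_f <- sum(stats::residuals(full)^2)
  rss_r <- sum(stats::residuals(red)^2)
  if (rss_f <= 1e-12 * max(rss_r, 1e-300)) {
    f <- Inf; p <- 0
  } else {
    f <- (rss_r - rss_f) / (rss_f / df)
    p <- stats::pf(f, 1, df, lower.tail = FALSE)
  }
  list(F = f, p = p, coefficients = stats::coef(full), df = df)
}

#' Two-sample t test
#'
#' Independent-samples t with pooled variance by default (df = nA + nB - 2);
#' Welch's unequal-variance variant by flag.
#'
#' @param vals_a,vals_b numeric samples (>= 2 each).
#' @param var_equal pooled variance (default) or Welch.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(vals_a, vals_b, var_equal = TRUE) {
  if (length(vals_a) < 2 || length(vals_b) < 2)
    stop("need at least 2 observations per group")
  if (var_equal && stats::var(vals_a) == 0 && stats::var(vals_b) == 0 &&
      mean(vals_a) == mean(vals_b))
    return(list(t = 0, p = 1, df = length(vals_a) + length(vals_b) - 2))
  tt <- stats::t.test(vals_a, vals_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Exclude subjects without small-world organization
#'
#' Retains subjects whose small-worldness index exceeds 1 (strictly); a
#' network with sigma <= 1 is not small-world and its metrics are not
#' comparable on the same footing. Exclusions are reported by id.
#'
#' @param sigma named numeric vector of per-subject sigma values.
#' @param groups group label per subject (same order).
#' @return list with `included` (ids), `excluded` (ids), `groups` (labels of
#'   the included subjects).
#' @export
small_world_filter <- function(sigma, groups) {
  ids <- names(sigma)
  if (is.null(ids)) ids <- as.character(seq_along(sigma))
  keep <- sigma > 1
  groups <- as.character(groups)
  for (gl in unique(groups))
    if (!any(keep[groups == gl]))
      stop("group eliminated by small-world exclusion: ", gl)
  if (any(!keep))
    message("excluded (sigma <= 1): ", paste(ids[!keep], collapse = ", "))
  list(included = ids[keep], excluded = ids[!keep], groups = groups[keep])
}
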