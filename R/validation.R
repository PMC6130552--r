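## simulation-based validation ------------------------------------------------
##
## One-replicate building blocks for the two simulation studies the package
## ships: calibration (type-I error of every inferential procedure on
## exchangeable null cohorts) and recovery (power to detect the planted
## disease-like fingerprint). Replicates are pure functions of their seed.

#' One null-cohort calibration replicate
#'
#' Generates an exchangeable two-group cohort (identical generator settings
#' for both groups) and runs every between-group inferential procedure on
#' it: the windowed-AUC permutation test (on raw clustering curves — the
#' permutation machinery is metric-agnostic), the network-based statistic in
#' both extent and intensity modes, and the power-law fit comparison. All
#' are permutation tests, exact under exchangeability; under the null each
#' p should be uniform. The parametric edge-wise FDR contrast has its own
#' replicate function ([fdr_calibration_replicate()]) because its t-based
#' p-values additionally require approximately normal edge weights.
#'
#' Calibration cohorts use 8 subjects per group: a 4 vs 4 design has only
#' 35 two-sided label-assignment atoms, capping the achievable type-I error
#' of any permutation test at 2/70 (about 0.029), so nominal-level
#' calibration can only be assessed where the permutation distribution is
#' effectively continuous. The NBS primary threshold defaults to 2 here so
#' the null suprathreshold graph (roughly 6% of edges) has non-degenerate
#' component-size variation — with a sparser graph the extent score ties at
#' 1-2 and the test is far from its nominal level by construction.
#'
#' @param seed replicate seed.
#' @param n_perm permutations per test (default 200 for simulation studies).
#' @param nbs_threshold primary |t| threshold for NBS calibration.
#' @param config generator configuration (default: the `"null"` preset with
#'   8 subjects per group).
#' @return named numeric vector: `auc_p`, `nbs_extent_p`, `nbs_intensity_p`,
#'   `powerlaw_p`.
#' @export
null_calibration_replicate <- function(seed, n_perm = 200L,
                                       nbs_threshold = 2,
                                       config = synth_preset("null",
                                                             per_group = 8L)) {
  coh <- gen_cohort(config, seed = seed, functional = FALSE)
  subs <- coh$subjects
  ga <- subs$id[subs$group == "A"]; gb <- subs$id[subs$group == "B"]
  grid <- density_grid(0.05, 0.30)
  grid <- grid[grid >= 0.15]
  curves <- metric_curves(coh$sc, grid, metrics = "C", seed = seed)
  auc <- auc_permutation_test(curves$C[ga, , drop = FALSE],
                              curves$C[gb, , drop = FALSE], grid,
                              c(min(grid), max(grid)), n_perm = n_perm,
                              seed = derive_seed(seed, 21), exact = FALSE)
  nets_a <- coh$sc[ga]; nets_b <- coh$sc[gb]
  nbs_e <- nbs_test(nets_a, nets_b, threshold = nbs_threshold,
                    mode = "extent", n_perm = n_perm,
                    seed = derive_seed(seed, 22))
  nbs_i <- nbs_test(nets_a, nets_b, threshold = nbs_threshold,
                    mode = "intensity", n_perm = n_perm,
                    seed = derive_seed(seed, 23))
  fits <- lapply(coh$sc, function(x)
    fit_power_law(node_strength(x), discrete = FALSE))
  pl <- compare_fit_between_groups(fits[ga], fits[gb], n_perm = n_perm,
                                   seed = derive_seed(seed, 24))
  c(auc_p = auc$p,
    nbs_extent_p = if (length(nbs_e$p_fwe)) min(nbs_e$p_fwe) else 1,
    nbs_intensity_p = if (length(nbs_i$p_fwe)) min(nbs_i$p_fwe) else 1,
    powerlaw_p = pl$p)
}

#' One edge-wise FDR calibration replicate
#'
#' The FDR contrast converts edge t statistics to p-values through the t
#' distribution, so its calibration additionally depends on approximately
#' normal edge weights — a small-sample tail approximation that bounded
#' FA-like structural weights violate at n = 4 per group. Calibration is
#' therefore assessed on functional connectomes (Fisher-z correlation
#' weights, close to normal) with 8 subjects per group, the same size the
#' component-level simulations use.
#'
#' @param seed replicate seed.
#' @param per_group subjects per group (default 8).
#' @param q FDR level.
#' @return 0/1: any edge discovered at level `q`.
#' @export
fdr_calibration_replicate <- function(seed, per_group = 8L, q = 0.05) {
  coh <- gen_cohort(synth_preset("null", per_group = per_group), seed = seed)
  subs <- coh$subjects
  fa <- coh$fc[subs$id[subs$group == "A"]]
  fb <- coh$fc[subs$id[subs$group == "B"]]
  as.numeric(nrow(fdr_edges(fa, fb, q = q)) > 0)
}

#' One planted-effect recovery replicate
#'
#' Generates a disease-like cohort (default: the `"fad_large"` preset) and
#' measures whether each planted deficit is detected with the procedure the
#' full analysis uses for it: upper-density-window AUC permutation tests for
#' normalized clustering, small-worldness, and modularity (group B planted
#' lower); the density-covaried linear model on weighted normalized path
#' length (group B planted higher); and the coupling t test (group B planted
#' higher). The upper window defaults to densities 0.34-0.5 on a 3-point
#' grid — the thresholded networks are identical across these densities for
#' the default generator (parent density 0.32), so the coarse grid changes
#' nothing about the AUC.
#'
#' @param seed replicate seed.
#' @param config generator configuration.
#' @param grid density grid for the upper-window curves.
#' @param n_random normalization nulls (default 20).
#' @param n_restarts Louvain restarts for Q curves (default 5 in simulation).
#' @return named numeric vector of detection indicators (`*_hit`: p < 0.05
#'   and effect in the planted direction) plus the raw p-values.
#' @export
recovery_replicate <- function(seed, config = synth_preset("fad_large"),
                               grid = c(0.34, 0.42, 0.50),
                               n_random = 20L, n_restarts = 5L) {
  coh <- gen_cohort(config, seed = seed)
  subs <- coh$subjects
  ga <- subs$id[subs$group == "A"]; gb <- subs$id[subs$group == "B"]
  curves <- metric_curves(coh$sc, grid, metrics = c("gamma", "sigma", "Q"),
                          n_random = n_random, n_restarts = n_restarts,
                          seed = derive_seed(seed, 31))
  window <- c(min(grid), max(grid))
  auc_p <- vapply(c("gamma", "sigma", "Q"), function(m) {
    res <- auc_permutation_test(curves[[m]][ga, , drop = FALSE],
                                curves[[m]][gb, , drop = FALSE],
                                grid, window, seed = derive_seed(seed, 32))
    # planted: group B below group A, so delta > 0
    if (res$delta > 0) res$p else 1
  }, 0)
  wa <- weighted_analysis(coh$sc, subs, n_random = n_random,
                          n_restarts = n_restarts,
                          seed = derive_seed(seed, 33),
                          exclude_non_smallworld = FALSE)
  lam <- wa$metrics
  lam_dir <- mean(lam$lambda[lam$group == "B"]) >
    mean(lam$lambda[lam$group == "A"])
  lam_p <- wa$tests$p[wa$tests$metric == "lambda"]
  r <- vapply(subs$id, function(id)
    predict_fc(coh$sc[[id]], coh$fc[[id]], "default")$r, 0)
  ct <- compare_coupling(r[ga], r[gb])
  coup_dir <- mean(r[gb]) > mean(r[ga])
  c(gamma_hit = as.numeric(auc_p["gamma"] < 0.05),
    sigma_hit = as.numeric(auc_p["sigma"] < 0.05),
    Q_hit = as.numeric(auc_p["Q"] < 0.05),
    lambda_hit = as.numeric(lam_dir && lam_p < 0.05),
    coupling_hit = as.numeric(coup_dir && ct$p < 0.05),
    gamma_p = unname(auc_p["gamma"]), sigma_p = unname(auc_p["sigma"]),
    Q_p = unname(auc_p["Q"]), lambda_p = lam_p, coupling_p = ct$p)
}
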