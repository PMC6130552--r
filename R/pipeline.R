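## full-study orchestration ---------------------------------------------------

#' Load a cohort from a manifest
#'
#' Reads each subject's time series and streamline tables and builds the
#' functional and structural connectomes.
#'
#' @param manifest path to a YAML manifest (see [load_manifest()]).
#' @param min_streamlines streamline threshold for structural edges.
#' @return list shaped like [gen_cohort()] output: `subjects`, `sc`, `fc`,
#'   `ts`, `structural`.
#' @export
load_cohort <- function(manifest, min_streamlines = 3) {
  man <- load_manifest(manifest)
  subs <- man$subjects
  read_mat <- function(path) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    dimnames(m) <- NULL
    m
  }
  sc <- fc <- ts <- structural <- vector("list", nrow(subs))
  for (i in seq_len(nrow(subs))) {
    cnt <- read_mat(subs$structural_counts[i])
    fa <- read_mat(subs$structural_fa[i])
    structural[[i]] <- list(counts = cnt, fa = fa, id = subs$id[i])
    sc[[i]] <- build_structural_connectome(cnt, fa,
                                           min_streamlines = min_streamlines)
    series <- read_mat(subs$functional[i])
    ts[[i]] <- series
    fc[[i]] <- build_functional_connectome(series)
  }
  names(sc) <- names(fc) <- names(ts) <- names(structural) <- subs$id
  list(subjects = subs[, c("id", "group")], structural = structural,
       sc = sc, fc = fc, ts = ts)
}

# split a named list of per-subject objects by group
.by_group <- function(objs, subjects) {
  split(objs[subjects$id], subjects$group)
}

#' Density-threshold analysis of one modality
#'
#' Finds the minimum connection density, computes normalized metric curves
#' up to the 0.5 density cap, derives the small-world window and the
#' group-curve crossover, and runs the windowed-AUC permutation tests.
#'
#' @param conns named list of weighted [connectome]s.
#' @param subjects data.frame with `id` and `group` columns.
#' @param step density grid step (default 0.01).
#' @param d_max density cap (default 0.5).
#' @param metrics metric curves to test.
#' @param n_random nulls per normalization (default 20).
#' @param n_restarts Louvain restarts (default 100).
#' @param n_perm AUC permutations (default 2000).
#' @param sw_rule small-world range rule, `"mean"` or `"all"`.
#' @param seed RNG seed.
#' @return list with `d_min`, `grid`, `curves`, `window_full`, `crossover`,
#'   and `tests` (data.frame: metric, window, delta, p).
#' @export
density_analysis <- function(conns, subjects, step = 0.01, d_max = 0.5,
                             metrics = c("lambda", "gamma", "sigma", "Q",
                                         "Eglob", "Eloc"),
                             n_random = 20L, n_restarts = 100L,
                             n_perm = 2000L, sw_rule = "mean", seed = 1L) {
  d_min <- minimum_connection_density(conns, step = step)
  grid <- density_grid(step, d_max)
  grid <- grid[grid >= d_min - 1e-9]
  curves <- metric_curves(conns, grid, metrics = unique(c(metrics, "sigma")),
                          n_random = n_random, n_restarts = n_restarts,
                          seed = seed)
  win_full <- small_world_density_range(curves$sigma, grid, d_min,
                                        d_max = d_max, rule = sw_rule)
  ga <- subjects$id[subjects$group == subjects$group[1]]
  gb <- subjects$id[subjects$group != subjects$group[1]]
  cross <- find_crossover(colMeans(curves$sigma[ga, , drop = FALSE]),
                          colMeans(curves$sigma[gb, , drop = FALSE]), grid)
  windows <- list(full = win_full)
  if (!is.null(cross) && cross > win_full$d_lo && cross < win_full$d_hi) {
    windows$lower <- density_window(win_full$d_lo, cross)
    windows$upper <- density_window(cross, win_full$d_hi)
  }
  tests <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(names(windows), function(wn) {
      res <- auc_permutation_test(curves[[m]][ga, , drop = FALSE],
                                  curves[[m]][gb, , drop = FALSE],
                                  grid, windows[[wn]], n_perm = n_perm,
                                  seed = derive_seed(seed, match(m, metrics),
                                                     match(wn, names(windows))))
      data.frame(metric = m, window = wn,
                 d_lo = windows[[wn]]$d_lo, d_hi = windows[[wn]]$d_hi,
                 delta = res$delta, p = res$p)
    }))
  }))
  list(d_min = d_min, grid = grid, curves = curves, windows = windows,
       crossover = cross, tests = tests)
}

#' Weighted-network analysis of one modality
#'
#' Computes the normalized metric set of each subject's weighted
#' (unthresholded) connectome, excludes subjects without small-world
#' organization, and compares each metric between groups with the
#' density-covaried linear model.
#'
#' @inheritParams density_analysis
#' @param exclude_non_smallworld apply the sigma > 1 filter first.
#' @return list with `metrics` (data.frame per subject), `excluded`, and
#'   `tests` (data.frame: metric, F, p).
#' @export
weighted_analysis <- function(conns, subjects, n_random = 20L,
                              n_restarts = 100L, seed = 1L,
                              exclude_non_smallworld = TRUE) {
  ids <- subjects$id
  rows <- lapply(seq_along(ids), function(i) {
    x <- conns[[ids[i]]]
    nulls <- random_reference(x$matrix, n_random = n_random,
                              seed = derive_seed(seed, i))
    ms <- metric_set(x$matrix, nulls, seed = derive_seed(seed, i, 2),
                     n_restarts = n_restarts)
    data.frame(id = ids[i], group = subjects$group[i], density = x$density,
               lambda = ms$lambda, gamma = ms$gamma, sigma = ms$sigma,
               L = ms$L, C = ms$C, Q = ms$Q, Eglob = ms$Eglob,
               Eloc = ms$Eloc)
  })
  tab <- do.call(rbind, rows)
  excluded <- character(0)
  if (exclude_non_smallworld) {
    flt <- small_world_filter(stats::setNames(tab$sigma, tab$id), tab$group)
    excluded <- flt$excluded
    tab <- tab[tab$id %in% flt$included, ]
  }
  tests <- do.call(rbind, lapply(
    c("lambda", "gamma", "sigma", "Q", "Eglob", "Eloc"), function(m) {
      res <- glm_group_test(tab[[m]], tab$group, tab$density)
      data.frame(metric = m, F = res$F, p = res$p)
    }))
  list(metrics = tab, excluded = excluded, tests = tests)
}

#' Structure-function coupling analysis
#'
#' Per subject, predicts weighted functional connectivity from structural
#' communication measures (default and all-measures models) and compares
#' the coupling correlations between groups.
#'
#' @param sc,fc named lists of structural and functional [connectome]s.
#' @param subjects data.frame with `id` and `group`.
#' @return list with `coupling` (data.frame: id, group, measures, r, p) and
#'   `tests` (data.frame: measures, t, p).
#' @export
coupling_analysis <- function(sc, fc, subjects) {
  rows <- list()
  for (ms in c("default", "all")) {
    for (i in seq_len(nrow(subjects))) {
      id <- subjects$id[i]
      res <- predict_fc(sc[[id]], fc[[id]], measures = ms)
      rows[[length(rows) + 1]] <- data.frame(
        id = id, group = subjects$group[i], measures = ms,
        r = res$r, p = res$p, n_pairs = res$n_pairs)
    }
  }
  coupling <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(c("default", "all"), function(ms) {
    sub <- coupling[coupling$measures == ms, ]
    gl <- unique(subjects$group)
    res <- compare_coupling(sub$r[sub$group == gl[1]],
                            sub$r[sub$group == gl[2]])
    data.frame(measures = ms, t = res$t, p = res$p)
  }))
  list(coupling = coupling, tests = tests)
}

#' Run the full two-group connectome comparison
#'
#' Orchestrates every stage on a cohort (from [gen_cohort()] or
#' [load_cohort()]): density-threshold AUC analysis per modality,
#' weighted-network density-covaried models, power-law degree-distribution
#' comparison, network-based statistic and edge-wise FDR, and
#' structure-function coupling. Every stochastic step is seeded
#' deterministically from `seed`.
#'
#' @param cohort cohort list (`subjects`, `sc`, `fc`).
#' @param step density grid step.
#' @param d_max density cap (default 0.5).
#' @param n_random normalization nulls (default 20).
#' @param n_restarts Louvain restarts (default 100).
#' @param n_perm permutations for AUC/NBS tests (default 2000).
#' @param nbs_threshold primary t threshold for NBS (default 3).
#' @param seed master seed.
#' @param out_dir optional directory for tidy CSV outputs.
#' @return nested list with elements `structural_density`,
#'   `functional_minimum_density`, `weighted_structural`,
#'   `weighted_functional`, `powerlaw`, `nbs`, `fdr`, `coupling`.
#' @export
run_full_pipeline <- function(cohort, step = 0.01, d_max = 0.5,
                              n_random = 20L, n_restarts = 100L,
                              n_perm = 2000L, nbs_threshold = 3,
                              seed = 1L, out_dir = NULL) {
  subs <- cohort$subjects
  res <- list()

  res$structural_density <- density_analysis(
    cohort$sc, subs, step = step, d_max = d_max, n_random = n_random,
    n_restarts = n_restarts, n_perm = n_perm, seed = derive_seed(seed, 1))

  # functional connectomes are dense; compare metrics at minimum connection
  # density after excluding subjects without small-world organization there
  d_min_f <- minimum_connection_density(cohort$fc, step = step)
  fmet <- lapply(seq_len(nrow(subs)), function(i) {
    net <- threshold_at_density(cohort$fc[[subs$id[i]]], d_min_f,
                                binarize = TRUE)
    nulls <- random_reference(net$matrix, n_random = n_random,
                              seed = derive_seed(seed, 2, i))
    normalized_metrics(net$matrix, nulls)
  })
  sig_f <- stats::setNames(vapply(fmet, `[[`, 0, "sigma"), subs$id)
  lam_f <- stats::setNames(vapply(fmet, `[[`, 0, "lambda"), subs$id)
  flt <- tryCatch(small_world_filter(sig_f, subs$group),
    error = function(e) {
      if (!grepl("eliminated", conditionMessage(e))) stop(e)
      message("small-world exclusion would eliminate a group at minimum ",
              "density; comparing all subjects")
      list(included = subs$id, excluded = character(0))
    })
  keep <- subs$id %in% flt$included
  gl <- unique(subs$group)
  tt <- two_sample_t(lam_f[keep & subs$group == gl[1]],
                     lam_f[keep & subs$group == gl[2]])
  res$functional_minimum_density <- list(
    d_min = d_min_f, sigma = sig_f, lambda = lam_f,
    excluded = flt$excluded, lambda_t = tt)

  # if the sigma filter would empty a group, fall back to the unfiltered
  # comparison and say so; the per-subject sigma values remain reported
  weighted_or_unfiltered <- function(conns, seed_part) {
    tryCatch(
      weighted_analysis(conns, subs, n_random = n_random,
                        n_restarts = n_restarts,
                        seed = derive_seed(seed, seed_part)),
      error = function(e) {
        if (!grepl("eliminated", conditionMessage(e))) stop(e)
        message("small-world exclusion would eliminate a group; ",
                "comparing without exclusion")
        out <- weighted_analysis(conns, subs, n_random = n_random,
                                 n_restarts = n_restarts,
                                 seed = derive_seed(seed, seed_part),
                                 exclude_non_smallworld = FALSE)
        out$note <- "sigma filter skipped: would eliminate a group"
        out
      })
  }
  res$weighted_structural <- weighted_or_unfiltered(cohort$sc, 3)
  res$weighted_functional <- weighted_or_unfiltered(cohort$fc, 4)

  # hub profile: strength-based fits on weighted graphs, per subject
  fits_by <- function(conns) lapply(conns, function(x)
    fit_power_law(node_strength(x), discrete = FALSE, min_tail = 10L))
  pl_s <- fits_by(cohort$sc[subs$id])
  pl_f <- fits_by(cohort$fc[subs$id])
  cmp <- function(fits) compare_fit_between_groups(
    fits[subs$group == gl[1]], fits[subs$group == gl[2]],
    n_perm = n_perm, seed = derive_seed(seed, 5))
  res$powerlaw <- list(structural_fits = pl_s, functional_fits = pl_f,
                       structural_p = cmp(pl_s)$p, functional_p = cmp(pl_f)$p)

  ga <- cohort$sc[subs$id[subs$group == gl[1]]]
  gb <- cohort$sc[subs$id[subs$group == gl[2]]]
  fa <- cohort$fc[subs$id[subs$group == gl[1]]]
  fb <- cohort$fc[subs$id[subs$group == gl[2]]]
  res$nbs <- list(
    structural_extent = nbs_test(ga, gb, threshold = nbs_threshold,
                                 mode = "extent", n_perm = n_perm,
                                 seed = derive_seed(seed, 6)),
    structural_intensity = nbs_test(ga, gb, threshold = nbs_threshold,
                                    mode = "intensity", n_perm = n_perm,
                                    seed = derive_seed(seed, 7)),
    functional_extent = nbs_test(fa, fb, threshold = nbs_threshold,
                                 mode = "extent", n_perm = n_perm,
                                 seed = derive_seed(seed, 8)),
    functional_intensity = nbs_test(fa, fb, threshold = nbs_threshold,
                                    mode = "intensity", n_perm = n_perm,
                                    seed = derive_seed(seed, 9)))
  res$fdr <- list(structural = fdr_edges(ga, gb),
                  functional = fdr_edges(fa, fb))

  res$coupling <- coupling_analysis(cohort$sc, cohort$fc, subs)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$structural_density$tests,
                     file.path(out_dir, "structural_auc_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(res$weighted_structural$tests,
                     file.path(out_dir, "weighted_structural_glm.csv"),
                     row.names = FALSE)
    utils::write.csv(res$weighted_functional$tests,
                     file.path(out_dir, "weighted_functional_glm.csv"),
                     row.names = FALSE)
    utils::write.csv(res$coupling$coupling,
                     file.path(out_dir, "coupling_per_subject.csv"),
                     row.names = FALSE)
    utils::write.csv(res$coupling$tests,
                     file.path(out_dir, "coupling_tests.csv"),
                     row.names = FALSE)
  }
  res
}

#' Recompute the in-vivo study quantities from supplementary matrices
#'
#' Given a directory holding the study's supplementary weighted network
#' matrices (one delimited 32 x 32 matrix per subject and modality, plus a
#' YAML manifest mapping subjects to groups and files with keys
#' `structural` and `functional`), recomputes: the minimum connection
#' densities, the functional path-length t statistic at minimum density
#' after small-world exclusion, the weighted-structural density-covaried F
#' statistics for lambda and sigma, the coupling t statistics (default and
#' all measures), and the number of subjects with significant default-model
#' coupling.
#'
#' @param data_dir directory with `manifest.yaml` and the matrices.
#' @param seed RNG seed for null-network normalization.
#' @return list of the recomputed quantities.
#' @export
reproduce_study_results <- function(data_dir, seed = 1L) {
  man_path <- file.path(data_dir, "manifest.yaml")
  if (!file.exists(man_path))
    stop("supplementary weighted network data not found under '", data_dir,
         "'; expected manifest.yaml plus per-subject matrices ",
         "(keys: structural, functional)")
  man <- load_manifest(man_path)
  subs <- man$subjects
  sc <- lapply(seq_len(nrow(subs)), function(i)
    read_connectome(subs$structural[i], modality = "structural"))
  fc <- lapply(seq_len(nrow(subs)), function(i)
    read_connectome(subs$functional[i], modality = "functional"))
  names(sc) <- names(fc) <- subs$id
  cohort <- list(subjects = subs[, c("id", "group")], sc = sc, fc = fc)
  res <- run_full_pipeline(cohort, seed = seed)
  coup <- res$coupling$coupling
  list(
    d_min_structural = res$structural_density$d_min,
    d_min_functional = res$functional_minimum_density$d_min,
    functional_lambda_t = res$functional_minimum_density$lambda_t$t,
    glm_F_lambda = res$weighted_structural$tests$F[
      res$weighted_structural$tests$metric == "lambda"],
    glm_F_sigma = res$weighted_structural$tests$F[
      res$weighted_structural$tests$metric == "sigma"],
    coupling_t_default = res$coupling$tests$t[
      res$coupling$tests$measures == "default"],
    coupling_t_all = res$coupling$tests$t[
      res$coupling$tests$measures == "all"],
    n_significant_default_coupling = sum(
      coup$p[coup$measures == "default"] < 0.05)
  )
}
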