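## synthetic two-group cohorts ------------------------------------------------
##
## Structural connectomes are Watts-Strogatz small-world graphs with
## FA-like Beta-distributed weights and integer streamline counts; the
## "disease-like" group gets a higher rewiring probability (degrading
## clustering, small-worldness, and modularity) and a weight deficit on a
## configurable edge class — by default edges incident to hub nodes, which
## raises the null-normalized weighted path length the way hub-targeting
## neurodegeneration would. Both effects keep density matched between
## groups, isolating topology/weight-organization effects the way the
## density-covaried group model assumes. Functional time series arise from
## a stable first-order diffusion recursion on the structural graph, giving
## tunable structure-function coupling; it is a statistical stand-in, not a
## hemodynamic model.

# deterministic 31-bit sub-seed from a master seed and offsets
derive_seed <- function(master, ...) {
  off <- sum(c(...) * 7919^(seq_along(c(...)) - 1))
  as.integer((as.numeric(master) * 69069 + off) %% 2147483647)
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the study conditions: 32 nodes, 4 subjects per group,
#' 450 functional volumes. Group-specific parameters are given as
#' `c(A = ..., B = ...)`; group B is the "disease-like" group under the
#' planted-effect presets.
#'
#' @param n_nodes nodes (default 32).
#' @param per_group subjects per group (default 4).
#' @param k ring-lattice neighbors (even; default 10, giving a structural
#'   density of 0.32 — dense enough that proportional thresholding across
#'   the analysis densities actually selects edges).
#' @param beta rewiring probability per group (default 0.1 both).
#' @param fa_shape1,fa_shape2 Beta law for FA-like weights (default
#'   Beta(9, 11): mean 0.45, realistic white-matter FA range).
#' @param n_modules contiguous lattice blocks treated as modules (default 4).
#' @param weight_deficit per group, multiplicative weight reduction applied
#'   to the edge class named by `deficit_scope` (0 = none).
#' @param deficit_scope which edges the deficit hits: `"hub"` (edges
#'   incident to the `n_hubs` highest-degree nodes; raises weighted,
#'   null-normalized path length), `"within"` (within-module edges), or
#'   `"between"` (between-module edges).
#' @param n_hubs number of top-degree nodes treated as hubs (default 8).
#' @param coupling per group, diffusion strength c in `[0, 1)` tying the
#'   functional series to the structural graph.
#' @param noise_sd innovation SD of the functional recursion.
#' @param t_len functional series length (default 450).
#' @param subthreshold_frac fraction of absent pairs given 1-2 spurious
#'   streamlines (removed by the count threshold downstream).
#' @export
synth_config <- function(n_nodes = 32L, per_group = 4L, k = 10L,
                         beta = c(A = 0.1, B = 0.1),
                         fa_shape1 = 9, fa_shape2 = 11, n_modules = 4L,
                         weight_deficit = c(A = 0, B = 0),
                         deficit_scope = c("hub", "within", "between"),
                         n_hubs = 8L,
                         coupling = c(A = 0.3, B = 0.3),
                         noise_sd = 1, t_len = 450L,
                         subthreshold_frac = 0.05) {
  deficit_scope <- match.arg(deficit_scope)
  stopifnot(k %% 2 == 0, k < n_nodes,
            all(beta >= 0 & beta <= 1), all(coupling >= 0 & coupling < 1),
            all(weight_deficit >= 0 & weight_deficit < 1))
  grp <- function(v) if (length(v) == 1) c(A = unname(v), B = unname(v)) else
    c(A = unname(v["A"]), B = unname(v["B"]))
  structure(list(n_nodes = as.integer(n_nodes),
                 per_group = as.integer(per_group), k = as.integer(k),
                 beta = grp(beta), fa_shape1 = fa_shape1,
                 fa_shape2 = fa_shape2, n_modules = as.integer(n_modules),
                 weight_deficit = grp(weight_deficit),
                 deficit_scope = deficit_scope, n_hubs = as.integer(n_hubs),
                 coupling = grp(coupling), noise_sd = noise_sd,
                 t_len = as.integer(t_len),
                 subthreshold_frac = subthreshold_frac),
            class = "synth_config")
}

#' Preset synthetic configurations
#'
#' `"null"`: both groups statistically exchangeable (calibration).
#' `"fad_large"`: large planted disease-like effect in group B — rewiring
#' 0.15 vs 0.05, hub-incident weight deficit 0.75, coupling 0.9 vs 0.2 —
#' each effect sized so the 4 vs 4 design detects it reliably (power above
#' 0.8) while group B stays small-world.
#'
#' @param name preset name.
#' @param ... overrides passed to [synth_config()].
#' @export
synth_preset <- function(name = c("null", "fad_large"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    null = list(),
    fad_large = list(beta = c(A = 0.05, B = 0.15),
                     weight_deficit = c(A = 0, B = 0.75),
                     deficit_scope = "hub",
                     coupling = c(A = 0.2, B = 0.9)))
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# connected Watts-Strogatz adjacency (binary), deterministic given the RNG state
.ws_graph <- function(n, k, beta) {
  for (i in 1:50) {
    g <- igraph::sample_smallworld(1, n, k / 2, beta)
    g <- igraph::simplify(g)
    if (igraph::components(g)$no == 1) return(g)
  }
  stop("failed to generate a connected small-world graph")
}

#' Generate one subject's streamline table
#'
#' @param config a [synth_config()].
#' @param group `"A"` or `"B"`.
#' @param subject subject index within the group.
#' @param seed master seed; the subject draw is a deterministic function of
#'   (seed, group, subject).
#' @return list with `counts`, `fa` (symmetric matrices), `id`.
#' @export
gen_structural <- function(config, group = c("A", "B"), subject = 1L,
                           seed = 1L) {
  group <- match.arg(group)
  n <- config$n_nodes
  set.seed(derive_seed(seed, match(group, c("A", "B")), subject, 1))
  g <- .ws_graph(n, config$k, config$beta[group])
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  m <- nrow(el)
  counts <- matrix(0L, n, n)
  counts[el] <- 3L + stats::rpois(m, 20)
  fa_vals <- stats::rbeta(m, config$fa_shape1, config$fa_shape2)
  deficit <- config$weight_deficit[group]
  if (deficit > 0) {
    sel <- switch(config$deficit_scope,
      hub = {
        deg <- tabulate(c(el), n)
        hubs <- order(deg, decreasing = TRUE)[seq_len(config$n_hubs)]
        el[, 1] %in% hubs | el[, 2] %in% hubs
      },
      within = {
        block <- ceiling(seq_len(n) / (n / config$n_modules))
        block[el[, 1]] == block[el[, 2]]
      },
      between = {
        block <- ceiling(seq_len(n) / (n / config$n_modules))
        block[el[, 1]] != block[el[, 2]]
      })
    fa_vals[sel] <- fa_vals[sel] * (1 - deficit)
  }
  fa <- matrix(0, n, n)
  fa[el] <- fa_vals
  # spurious sub-threshold streamlines on a few absent pairs
  pairs <- ut_pairs(n)
  absent <- which(counts[pairs] == 0)
  n_spur <- round(config$subthreshold_frac * length(absent))
  if (n_spur > 0) {
    spur <- sample(absent, n_spur)
    counts[pairs[spur, , drop = FALSE]] <- sample(1:2, n_spur, replace = TRUE)
    fa[pairs[spur, , drop = FALSE]] <-
      stats::rbeta(n_spur, config$fa_shape1, config$fa_shape2)
  }
  counts <- counts + t(counts); fa <- fa + t(fa)
  labels <- paste0("R", seq_len(n))
  dimnames(counts) <- dimnames(fa) <- list(labels, labels)
  list(counts = counts, fa = fa,
       id = sprintf("%s%d", tolower(group), subject))
}

#' Generate one subject's functional time series
#'
#' First-order diffusion on the structural graph:
#' `x_t = c * W_rn %*% x_{t-1} + noise`, with `W_rn` the row-normalized
#' structural weights and `c` the group's coupling strength (c < 1 keeps
#' the recursion stable). At c = 0 regions are independent noise; rising c
#' makes the functional correlation structure follow the structural
#' communication structure.
#'
#' @param sc structural [connectome] or adjacency matrix.
#' @param config a [synth_config()].
#' @inheritParams gen_structural
#' @return regions x timepoints matrix.
#' @export
gen_functional <- function(sc, config, group = c("A", "B"), subject = 1L,
                           seed = 1L) {
  group <- match.arg(group)
  w <- as_adj(sc)
  n <- nrow(w)
  if (any(rowSums(w) == 0)) stop("structural graph has an isolated node")
  cc <- config$coupling[group]
  A <- cc * w / rowSums(w)
  set.seed(derive_seed(seed, match(group, c("A", "B")), subject, 2))
  burn <- 50L
  t_tot <- config$t_len + burn
  x <- matrix(0, n, t_tot)
  x[, 1] <- stats::rnorm(n, sd = config$noise_sd)
  for (t in 2:t_tot)
    x[, t] <- A %*% x[, t - 1] + stats::rnorm(n, sd = config$noise_sd)
  out <- x[, (burn + 1):t_tot, drop = FALSE]
  rownames(out) <- paste0("R", seq_len(n))
  out
}

#' Generate a full two-group cohort
#'
#' Produces per-subject streamline tables, structural connectomes, and
#' coupled functional time series; optionally writes everything (matrices,
#' label sidecar, YAML manifest) to `dir`. Fully reproducible: per-subject
#' seeds are derived deterministically from the master seed.
#'
#' @param config a [synth_config()].
#' @param seed master seed.
#' @param dir output directory (created; must not already contain a
#'   manifest). `NULL` keeps the cohort in memory.
#' @param functional also simulate functional series (default TRUE; turn off
#'   for structure-only simulation studies).
#' @return list with `subjects` (data.frame id/group), `structural` (list of
#'   streamline tables), `sc` (structural [connectome]s), `ts` (time-series
#'   matrices), `fc` (functional [connectome]s), `config`, `seed`, and
#'   `manifest` (path, when written).
#' @export
gen_cohort <- function(config, seed = 1L, dir = NULL, functional = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(dir) && !functional)
    stop("writing a cohort requires the functional series")
  groups <- rep(c("A", "B"), each = config$per_group)
  idx <- rep(seq_len(config$per_group), 2)
  structural <- sc <- ts <- fc <- vector("list", length(groups))
  ids <- character(length(groups))
  for (i in seq_along(groups)) {
    st <- gen_structural(config, groups[i], idx[i], seed)
    conn <- build_structural_connectome(st$counts, st$fa)
    structural[[i]] <- st; sc[[i]] <- conn
    ids[i] <- st$id
    if (functional) {
      series <- gen_functional(conn, config, groups[i], idx[i], seed)
      ts[[i]] <- series
      fc[[i]] <- build_functional_connectome(series)
    }
  }
  names(structural) <- names(sc) <- names(ts) <- names(fc) <- ids
  out <- list(subjects = data.frame(id = ids, group = groups,
                                    stringsAsFactors = FALSE),
              structural = structural, sc = sc, ts = ts, fc = fc,
              config = config, seed = seed)
  if (!is.null(dir)) {
    if (file.exists(file.path(dir, "manifest.yaml")))
      stop("output directory already holds a cohort: ", dir)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(paste0("R", seq_len(config$n_nodes)),
               file.path(dir, "labels.txt"))
    write_mat <- function(m, f) writeLines(
      apply(format(m, digits = 17, trim = TRUE, scientific = TRUE),
            1, paste, collapse = "\t"), file.path(dir, f))
    entries <- lapply(seq_along(ids), function(i) {
      write_mat(structural[[i]]$counts, paste0(ids[i], "_counts.tsv"))
      write_mat(structural[[i]]$fa, paste0(ids[i], "_fa.tsv"))
      write_mat(ts[[i]], paste0(ids[i], "_ts.tsv"))
      list(id = ids[i], group = groups[i],
           functional = paste0(ids[i], "_ts.tsv"),
           structural_counts = paste0(ids[i], "_counts.tsv"),
           structural_fa = paste0(ids[i], "_fa.tsv"))
    })
    yaml::write_yaml(list(seed = seed, subjects = entries),
                     file.path(dir, "manifest.yaml"))
    out$manifest <- file.path(dir, "manifest.yaml")
  }
  out
}
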