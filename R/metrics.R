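## graph metrics ------------------------------------------------------------
##
## All metrics accept either a `connectome` or a plain symmetric adjacency
## matrix. Weighted path metrics use the standard length = 1/weight mapping;
## weighted clustering uses the Onnela geometric-mean triangle formula on
## max-normalized weights (the toolbox convention in connectomics).

as_adj <- function(x) {
  if (inherits(x, "connectome")) x$matrix
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a connectome or a numeric matrix")
}

# edge-list construction: much faster than graph_from_adjacency_matrix
.graph_of <- function(mat) {
  n <- nrow(mat)
  pairs <- ut_pairs(n)
  w <- mat[pairs]
  keep <- w > 0
  g <- igraph::make_graph(t(pairs[keep, , drop = FALSE]), n = n,
                          directed = FALSE)
  igraph::E(g)$weight <- w[keep]
  g
}

# all-pairs shortest path lengths of a binary adjacency by BFS level sets
.apsp_binary <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  reach <- a > 0
  diag(reach) <- TRUE
  l <- 1
  while (l < n) {
    nxt <- (reach %*% a) > 0 | reach
    new <- nxt & !reach
    if (!any(new)) break
    l <- l + 1
    d[new] <- l
    reach <- nxt
  }
  d
}

is_binary_adj <- function(mat) all(mat %in% c(0, 1))

#' Node degree and strength
#'
#' @param x connectome or adjacency matrix.
#' @return `node_degree`: integer count of neighbors per node;
#'   `node_strength`: sum of edge weights per node.
#' @export
node_degree <- function(x) {
  mat <- as_adj(x)
  as.integer(rowSums(mat > 0))
}

#' @rdname node_degree
#' @export
node_strength <- function(x) {
  rowSums(as_adj(x))
}

#' All-pairs shortest path lengths
#'
#' Binary networks use unit edge lengths; weighted networks map each weight
#' w to a length 1/w, so stronger connections are shorter. Unreachable pairs
#' get `Inf`.
#'
#' @param x connectome or adjacency matrix (nonnegative weights).
#' @return an N x N matrix of shortest path lengths (zero diagonal).
#' @export
shortest_path_lengths <- function(x) {
  mat <- as_adj(x)
  if (is_binary_adj(mat)) {
    d <- .apsp_binary(mat)
  } else {
    g <- .graph_of(mat)
    w <- igraph::E(g)$weight
    d <- igraph::distances(g, weights = 1 / w, algorithm = "dijkstra")
  }
  dimnames(d) <- dimnames(mat)
  d
}

#' Characteristic path length
#'
#' Mean shortest path length over node pairs. For disconnected networks the
#' mean is taken over finite distances only (with a warning); the analysis
#' pipeline avoids this case by restricting densities to the minimum
#' connection density and above.
#'
#' @inheritParams shortest_path_lengths
#' @param warn_disconnected warn when infinite distances are dropped.
#' @export
characteristic_path_length <- function(x, warn_disconnected = TRUE) {
  d <- shortest_path_lengths(x)
  v <- d[upper.tri(d)]
  fin <- is.finite(v)
  if (!any(fin)) stop("fully disconnected network: no finite path")
  if (!all(fin) && warn_disconnected)
    warning("disconnected network: path length averaged over finite pairs only")
  mean(v[fin])
}

#' Clustering coefficient
#'
#' Binary: mean over nodes of (closed triangles)/(possible triangles); nodes
#' with degree < 2 contribute 0. Weighted: Onnela's geometric-mean triangle
#' intensity on weights normalized by the network maximum, with the same
#' binary-degree denominator.
#'
#' @inheritParams shortest_path_lengths
#' @export
clustering_coefficient <- function(x) {
  mat <- as_adj(x)
  if (nrow(mat) < 3) stop("clustering needs at least 3 nodes")
  a <- (mat > 0) + 0
  k <- rowSums(a)
  if (is_binary_adj(mat)) {
    tri <- diag(a %*% a %*% a) / 2
  } else {
    w3 <- (mat / max(mat))^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3) / 2
  }
  denom <- k * (k - 1) / 2
  c_i <- ifelse(k >= 2, tri / denom, 0)
  mean(c_i)
}

#' Global efficiency
#'
#' Mean inverse shortest path length over all node pairs; unreachable pairs
#' contribute 0, so efficiency is defined for disconnected networks.
#'
#' @inheritParams shortest_path_lengths
#' @export
global_efficiency <- function(x) {
  d <- shortest_path_lengths(x)
  v <- d[upper.tri(d)]
  if (!length(v)) return(0)
  mean(1 / v)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors (the node itself removed); nodes with fewer than two
#' neighbors contribute 0.
#'
#' @inheritParams shortest_path_lengths
#' @export
local_efficiency <- function(x) {
  mat <- as_adj(x)
  n <- nrow(mat)
  e <- vapply(seq_len(n), function(i) {
    nb <- which(mat[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(mat[nb, nb, drop = FALSE])
  }, 0)
  mean(e)
}

#' Modularity by seeded multi-restart Louvain
#'
#' Decomposes the network into non-overlapping modules with maximal
#' within-module and minimal between-module connectivity (Newman modularity
#' Q, weighted where applicable). Louvain is stochastic, so `n_restarts`
#' seeded runs are performed and the maximum-Q partition returned.
#'
#' @inheritParams shortest_path_lengths
#' @param seed base seed; restart i uses `seed + i`.
#' @param n_restarts number of Louvain restarts (default 100).
#' @return list with `membership` (integer module id per node), `Q`, `seed`.
#' @export
modularity_partition <- function(x, seed = 1L, n_restarts = 100L) {
  mat <- as_adj(x)
  if (all(mat == 0)) stop("modularity undefined for an empty graph")
  g <- .graph_of(mat)
  w <- igraph::E(g)$weight
  best <- NULL; best_q <- -Inf
  for (i in seq_len(n_restarts)) {
    set.seed(seed + i)
    cl <- igraph::cluster_louvain(g, weights = w)
    q <- igraph::modularity(g, igraph::membership(cl), weights = w)
    if (q > best_q) { best_q <- q; best <- as.integer(igraph::membership(cl)) }
  }
  list(membership = best, Q = best_q, seed = seed)
}

#' Degree-preserving random reference networks
#'
#' Maslov-Sneppen rewiring (10 attempted edge swaps per edge) preserves the
#' degree sequence exactly while destroying topology. For weighted networks
#' the topology is rewired first, then the original multiset of weights is
#' reassigned to the new edges in random order, preserving the weight
#' distribution exactly.
#'
#' @inheritParams shortest_path_lengths
#' @param n_random number of null networks (default 20).
#' @param seed base seed; null i uses `seed + i`.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @return list of adjacency matrices.
#' @export
random_reference <- function(x, n_random = 20L, seed = 1L,
                             swaps_per_edge = 10L) {
  mat <- as_adj(x)
  n <- nrow(mat)
  pairs <- ut_pairs(n)
  w_ut <- mat[pairs]
  m <- sum(w_ut > 0)
  if (m < 2) {
    warning("too few edges to rewire; returning copies of the original")
    return(replicate(n_random, mat, simplify = FALSE))
  }
  g <- .graph_of(mat)
  weights <- igraph::E(g)$weight
  weighted <- !is_binary_adj(mat)
  lapply(seq_len(n_random), function(i) {
    set.seed(seed + i)
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = swaps_per_edge * m))
    el <- igraph::as_edgelist(gr, names = FALSE)
    out <- matrix(0, n, n)
    wts <- if (weighted) sample(weights) else rep(1, m)
    out[el] <- wts
    out <- out + t(out)
    dimnames(out) <- dimnames(mat)
    out
  })
}

#' Random-network-normalized path length, clustering, and small-worldness
#'
#' lambda = L / mean(L of nulls), gamma = C / mean(C of nulls), and the
#' small-worldness index sigma = gamma / lambda. Values of sigma above 1
#' indicate small-world organization: clustering well above random with
#' near-random path length.
#'
#' @inheritParams shortest_path_lengths
#' @param nulls list of null adjacency matrices from [random_reference()].
#' @return list with `lambda`, `gamma`, `sigma`, and the raw `L`, `C`.
#' @export
normalized_metrics <- function(x, nulls) {
  if (!length(nulls)) stop("need at least one null network")
  L <- characteristic_path_length(x, warn_disconnected = FALSE)
  C <- clustering_coefficient(x)
  L0 <- mean(vapply(nulls, characteristic_path_length,
                    0, warn_disconnected = FALSE))
  C0 <- mean(vapply(nulls, clustering_coefficient, 0))
  if (L0 == 0 || C0 == 0) stop("null network metric is zero; cannot normalize")
  lambda <- L / L0
  gamma <- C / C0
  list(lambda = lambda, gamma = gamma, sigma = gamma / lambda, L = L, C = C)
}

#' Full metric set of one network
#'
#' @inheritParams normalized_metrics
#' @param seed seed for the Louvain restarts.
#' @param n_restarts Louvain restarts.
#' @return list with lambda, gamma, sigma, L, C, Eglob, Eloc, Q, degree,
#'   strength.
#' @export
metric_set <- function(x, nulls, seed = 1L, n_restarts = 100L) {
  nm <- normalized_metrics(x, nulls)
  mod <- modularity_partition(x, seed = seed, n_restarts = n_restarts)
  c(nm, list(
    Eglob = global_efficiency(x),
    Eloc = local_efficiency(x),
    Q = mod$Q,
    membership = mod$membership,
    degree = node_degree(x),
    strength = node_strength(x)
  ))
}

#' Metric curves across a density grid
#'
#' Thresholds each subject's connectome at every grid density and computes
#' the requested metrics, normalizing lambda/gamma/sigma by `n_random`
#' degree-preserving nulls per subject and density (seeded deterministically
#' from `seed`, subject, and density, so curves are reproducible).
#'
#' @param conns named list of weighted [connectome]s.
#' @param grid density grid (see [density_grid()]).
#' @param metrics subset of `c("lambda","gamma","sigma","L","C","Q","Eglob","Eloc")`.
#' @param binarize analyze binarized thresholded networks (default TRUE).
#' @param n_random nulls per normalization (default 20).
#' @param n_restarts Louvain restarts for Q (default 100).
#' @param seed base seed.
#' @return named list of subjects x densities matrices, one per metric.
#' @export
metric_curves <- function(conns, grid,
                          metrics = c("lambda", "gamma", "sigma", "Q",
                                      "Eglob", "Eloc"),
                          binarize = TRUE, n_random = 20L,
                          n_restarts = 100L, seed = 1L) {
  metrics <- match.arg(metrics, c("lambda", "gamma", "sigma", "L", "C", "Q",
                                  "Eglob", "Eloc"), several.ok = TRUE)
  need_norm <- any(metrics %in% c("lambda", "gamma", "sigma"))
  ns <- length(conns); nd <- length(grid)
  out <- lapply(metrics, function(m) {
    mat <- matrix(NA_real_, ns, nd,
                  dimnames = list(names(conns), sprintf("%.2f", grid)))
    mat
  })
  names(out) <- metrics
  for (s in seq_len(ns)) {
    for (j in seq_len(nd)) {
      net <- threshold_at_density(conns[[s]], grid[j], binarize = binarize)
      mat <- net$matrix
      sd_seed <- (seed + s * 1000L + j) %% .Machine$integer.max
      if (need_norm) {
        nulls <- random_reference(mat, n_random = n_random, seed = sd_seed)
        nm <- normalized_metrics(mat, nulls)
      } else {
        nm <- list(L = if ("L" %in% metrics)
          characteristic_path_length(mat, warn_disconnected = FALSE) else NA,
          C = if ("C" %in% metrics) clustering_coefficient(mat) else NA)
      }
      for (m in metrics) {
        out[[m]][s, j] <- switch(m,
          lambda = nm$lambda, gamma = nm$gamma, sigma = nm$sigma,
          L = nm$L, C = nm$C,
          Q = modularity_partition(mat, seed = sd_seed,
                                   n_restarts = n_restarts)$Q,
          Eglob = global_efficiency(mat),
          Eloc = local_efficiency(mat))
      }
    }
  }
  out
}
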