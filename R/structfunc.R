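## structure-function coupling -----------------------------------------------
##
## Communication measures computed on the structural connectome serve as
## predictors of functional connectivity in a per-subject regression over
## node pairs; the Pearson correlation between predicted and observed FC
## quantifies structure-function coupling.

# shortest-path node sequences from every source (lengths = 1/weight);
# list indexed [[from]][[to]]; NULL where unreachable
.all_shortest_path_nodes <- function(mat) {
  g <- .graph_of(mat)
  w <- 1 / igraph::E(g)$weight
  n <- nrow(mat)
  lapply(seq_len(n), function(s) {
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = s, to = igraph::V(g), weights = w,
                             output = "vpath"))
    lapply(sp$vpath, function(v) {
      v <- as.integer(v)
      if (length(v) < 1) NULL else v
    })
  })
}

#' Matching index
#'
#' Similarity of two nodes' connection profiles: the connectivity they share
#' through common neighbors (excluding the pair itself), relative to their
#' total connectivity. Weighted; 1 for identical neighborhoods, 0 for
#' disjoint ones.
#'
#' @param x connectome or adjacency matrix.
#' @return symmetric N x N matrix in `[0, 1]` (zero diagonal).
#' @export
matching_index <- function(x) {
  w <- as_adj(x)
  n <- nrow(w)
  a <- (w > 0) + 0
  mi <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- setdiff(seq_len(n), c(i, j))
    shared <- a[i, k] * a[j, k]
    num <- sum((w[i, k] + w[j, k]) * shared)
    den <- sum(w[i, k] * a[i, k] + w[j, k] * a[j, k])
    if (den > 0) mi[i, j] <- mi[j, i] <- num / den
  }
  dimnames(mi) <- dimnames(w)
  mi
}

#' Neighborhood overlap
#'
#' Jaccard index of the two nodes' binarized neighbor sets (the pair itself
#' excluded): shared neighbors / union of neighbors.
#'
#' @inheritParams matching_index
#' @return symmetric N x N matrix in `[0, 1]` (zero diagonal).
#' @export
neighborhood_overlap <- function(x) {
  a <- (as_adj(x) > 0) + 0
  n <- nrow(a)
  no <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- setdiff(seq_len(n), c(i, j))
    inter <- sum(a[i, k] & a[j, k])
    uni <- sum(a[i, k] | a[j, k])
    if (uni > 0) no[i, j] <- no[j, i] <- inter / uni
  }
  dimnames(no) <- dimnames(as_adj(x))
  no
}

#' Search information of shortest paths
#'
#' The information (bits) a memoryless random walker needs to follow the
#' shortest path from s to t: minus log2 of the product over path steps of
#' (step weight / strength of the current node). Asymmetric in general;
#' unreachable pairs get `Inf`.
#'
#' @inheritParams matching_index
#' @return N x N matrix of bits (zero diagonal).
#' @export
search_information <- function(x) {
  w <- as_adj(x)
  n <- nrow(w)
  s <- rowSums(w)
  paths <- .all_shortest_path_nodes(w)
  si <- matrix(Inf, n, n)
  diag(si) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- paths[[i]][[j]]
    if (is.null(v) || length(v) < 2 || v[length(v)] != j) next
    steps <- cbind(v[-length(v)], v[-1])
    logp <- sum(log2(w[steps]) - log2(s[v[-length(v)]]))
    si[i, j] <- -logp
  }
  dimnames(si) <- dimnames(w)
  si
}

#' Path transitivity
#'
#' For the shortest path from s to t with node sequence pi_1..pi_Omega, the
#' mean matching index over all node pairs on the path: the density of local
#' detours available along the route. For adjacent nodes (a two-node path)
#' this reduces to their matching index.
#'
#' @inheritParams matching_index
#' @return symmetric N x N matrix in `[0, 1]` (zero diagonal; `NA` for
#'   unreachable pairs).
#' @export
path_transitivity <- function(x) {
  w <- as_adj(x)
  n <- nrow(w)
  mi <- matching_index(w)
  paths <- .all_shortest_path_nodes(w)
  pt <- matrix(NA_real_, n, n)
  diag(pt) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- paths[[i]][[j]]
    if (is.null(v) || length(v) < 2 || v[length(v)] != j) next
    omega <- length(v)
    prs <- utils::combn(v, 2)
    pt[i, j] <- pt[j, i] <- 2 / (omega * (omega - 1)) *
      sum(mi[cbind(prs[1, ], prs[2, ])])
  }
  dimnames(pt) <- dimnames(w)
  pt
}

#' Column-wise z-scored mean first passage time
#'
#' Expected number of steps for the weighted random walk (transition
#' probabilities w_ij / strength_i) to first reach each target node,
#' computed from the fundamental matrix of the chain, then z-scored within
#' each target column over its off-diagonal entries (so targets are
#' comparable despite different stationary visit rates). A single-entry
#' column z-scores to 0 (only possible at N = 2).
#'
#' @inheritParams matching_index
#' @param zscore return the column z-scored matrix (default) or raw MFPT.
#' @return N x N matrix (zero diagonal).
#' @export
mean_first_passage_time <- function(x, zscore = TRUE) {
  w <- as_adj(x)
  n <- nrow(w)
  s <- rowSums(w)
  if (any(s == 0)) stop("isolated node: random walk undefined")
  g <- .graph_of(w)
  if (igraph::components(g)$no > 1) stop("disconnected network: MFPT undefined")
  P <- w / s
  pi_st <- s / sum(s)
  Z <- solve(diag(n) - P + matrix(pi_st, n, n, byrow = TRUE))
  mfpt <- (matrix(diag(Z), n, n, byrow = TRUE) - Z) /
    matrix(pi_st, n, n, byrow = TRUE)
  diag(mfpt) <- 0
  if (!zscore) { dimnames(mfpt) <- dimnames(w); return(mfpt) }
  out <- mfpt
  for (j in seq_len(n)) {
    v <- mfpt[-j, j]
    out[-j, j] <- if (length(v) < 2 || stats::sd(v) == 0) 0 else
      (v - mean(v)) / stats::sd(v)
  }
  dimnames(out) <- dimnames(w)
  out
}

#' Communication measure set of a structural connectome
#'
#' The default set holds the two canonical predictors of functional from
#' structural connectivity: weighted shortest path length and (symmetrized)
#' search information. The full set adds path transitivity, column-wise
#' z-scored mean first passage time (symmetrized), neighborhood overlap, and
#' matching index.
#'
#' @inheritParams matching_index
#' @param subset `"default"` or `"all"`.
#' @return named list of N x N predictor matrices.
#' @export
comm_measures <- function(x, subset = c("default", "all")) {
  subset <- match.arg(subset)
  w <- as_adj(x)
  si <- search_information(w)
  out <- list(SPL = shortest_path_lengths(w), SI = (si + t(si)) / 2)
  if (subset == "all") {
    mz <- mean_first_passage_time(w)
    out$PT <- path_transitivity(w)
    out$MFPTz <- (mz + t(mz)) / 2
    out$NO <- neighborhood_overlap(w)
    out$MI <- matching_index(w)
  }
  out
}

#' Predict functional from structural connectivity
#'
#' Per subject, regresses observed functional connectivity on the structural
#' communication measures over node pairs (ordinary least squares on the
#' upper triangle), builds the predicted FC matrix from the fitted values,
#' and reports the Pearson correlation r between predicted and observed FC
#' with its p-value. Structurally unreachable pairs are excluded (their
#' measures are undefined); collinear predictors are dropped with a warning.
#'
#' @param sc structural [connectome] (or matrix).
#' @param fc functional [connectome] (or matrix) on the same node set.
#' @param measures `"default"` or `"all"`, or a precomputed [comm_measures()]
#'   list.
#' @param include_zero_fc keep pairs whose observed FC is zero (zeroed
#'   negative correlations) as responses (default TRUE).
#' @return list of class `coupling_result`: `r`, `p`, `coefficients`,
#'   `n_pairs`, `n_excluded`, `measures`, `predicted` (matrix), `observed`.
#' @export
predict_fc <- function(sc, fc, measures = c("default", "all"),
                       include_zero_fc = TRUE) {
  scm <- as_adj(sc); fcm <- as_adj(fc)
  if (!all(dim(scm) == dim(fcm))) stop("SC and FC node sets differ")
  if (is.character(measures)) {
    subset <- match.arg(measures)
    measures <- comm_measures(scm, subset)
  } else subset <- paste(names(measures), collapse = "+")
  n <- nrow(scm)
  X <- vapply(measures, ut_vec, numeric(n * (n - 1) / 2))
  y <- ut_vec(fcm)
  use <- apply(X, 1, function(r) all(is.finite(r)))
  if (!include_zero_fc) use <- use & y != 0
  n_excluded <- sum(!use)
  if (sum(use) <= ncol(X) + 2) stop("too few usable node pairs for regression")
  dat <- data.frame(y = y[use], X[use, , drop = FALSE])
  fit <- stats::lm(y ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    warning("collinear predictor(s) dropped: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  pred <- stats::fitted(fit)
  ct <- stats::cor.test(pred, dat$y)
  pred_mat <- matrix(NA_real_, n, n)
  pv <- rep(NA_real_, length(y)); pv[use] <- pred
  pred_mat[upper.tri(pred_mat)] <- pv
  pred_mat[lower.tri(pred_mat)] <- t(pred_mat)[lower.tri(pred_mat)]
  diag(pred_mat) <- 0
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 coefficients = cf, n_pairs = sum(use),
                 n_excluded = n_excluded, measures = subset,
                 predicted = pred_mat, observed = fcm),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> %s measures: r = %.3f (p = %.3g, %d pairs)\n",
              x$measures, x$r, x$p, x$n_pairs))
  invisible(x)
}

#' Compare structure-function coupling between groups
#'
#' Two-sample t test on per-subject coupling correlations, Fisher
#' z-transformed by default so the statistic is computed on an
#' approximately variance-stabilized scale.
#'
#' @param r_a,r_b per-subject coupling r values for the two groups.
#' @param fisher transform r with atanh first (default TRUE).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return list with `t`, `p`, `df`.
#' @export
compare_coupling <- function(r_a, r_b, fisher = TRUE, var_equal = TRUE) {
  if (fisher) { r_a <- atanh(r_a); r_b <- atanh(r_b) }
  two_sample_t(r_a, r_b, var_equal = var_equal)
}
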