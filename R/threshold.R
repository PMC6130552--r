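#' Density grid
#'
#' Ordered density values `step, 2*step, ..., <= d_max`. The default step of
#' 0.01 makes the densities commonly reported for connectome analyses (0.24,
#' 0.34, 0.40, 0.50) exact grid points.
#'
#' @param step grid step (default 0.01).
#' @param d_max upper limit (default 1).
#' @export
density_grid <- function(step = 0.01, d_max = 1) {
  g <- seq(step, d_max, by = step)
  round(g, 10)
}

#' Proportional thresholding at a target density
#'
#' Retains the `floor(d * N(N-1)/2)` strongest edges of a weighted
#' connectome. Ties are broken deterministically: stable sort by weight
#' descending, then by (row, column) lexicographic order, so results are
#' identical across runs and platforms.
#'
#' @param conn a weighted [connectome].
#' @param d target density in (0, 1].
#' @param binarize set retained weights to 1.
#' @return a [connectome] at (up to) the target density; achieved density can
#'   fall below target when the parent has fewer edges.
#' @export
threshold_at_density <- function(conn, d, binarize = FALSE) {
  stopifnot(inherits(conn, "connectome"))
  if (d <= 0 || d > 1) stop("density must lie in (0, 1], got ", d)
  n <- conn$n_nodes
  m_possible <- n * (n - 1) / 2
  keep_n <- floor(d * m_possible + 1e-9)
  if (keep_n < 1) stop("density ", d, " is below the density of a single edge")
  pairs <- ut_pairs(n)
  w <- conn$matrix[pairs]
  present <- which(w > 0)
  ord <- present[order(-w[present], pairs[present, 1], pairs[present, 2])]
  keep <- ord[seq_len(min(keep_n, length(ord)))]
  v <- numeric(m_possible)
  v[keep] <- if (binarize) 1 else w[keep]
  connectome(sym_from_ut(v, n), conn$labels, modality = conn$modality,
             weighted = !binarize)
}

# smallest number of strongest edges making conn connected, or NA
.min_edges_connected <- function(conn) {
  n <- conn$n_nodes
  pairs <- ut_pairs(n)
  w <- conn$matrix[pairs]
  present <- which(w > 0)
  if (!length(present)) return(NA_integer_)
  ord <- present[order(-w[present], pairs[present, 1], pairs[present, 2])]
  g_full <- igraph::graph_from_edgelist(pairs[ord, , drop = FALSE],
                                        directed = FALSE)
  if (igraph::vcount(g_full) < n ||
      igraph::components(g_full)$no > 1) return(NA_integer_)
  lo <- n - 1L; hi <- length(ord)
  while (lo < hi) {                       # connectivity is monotone in edge count
    mid <- (lo + hi) %/% 2L
    g <- igraph::graph_from_edgelist(pairs[ord[seq_len(mid)], , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    if (igraph::components(g)$no == 1L) hi <- mid else lo <- mid + 1L
  }
  lo
}

#' Minimum connection density of a cohort
#'
#' The smallest grid density at which every subject's proportionally
#' thresholded network forms a single connected component. Analyses over
#' density are restricted to start here so path-based metrics are defined
#' for all subjects.
#'
#' @param conns list of weighted [connectome]s (same N).
#' @param step density grid step (default 0.01).
#' @return the minimum connection density (a grid value).
#' @export
minimum_connection_density <- function(conns, step = 0.01) {
  stopifnot(length(conns) >= 1)
  n <- conns[[1]]$n_nodes
  if (!all(vapply(conns, function(c) c$n_nodes, 0L) == n))
    stop("all connectomes must have the same number of nodes")
  m_possible <- n * (n - 1) / 2
  need <- vapply(conns, .min_edges_connected, 0L)
  if (anyNA(need)) {
    ids <- which(is.na(need))
    stop("subject(s) disconnected even at density 1: index ",
         paste(ids, collapse = ", "))
  }
  grid <- density_grid(step)
  # first grid density whose retained-edge count covers the worst subject
  d <- grid[floor(grid * m_possible + 1e-9) >= max(need)][1]
  if (is.na(d)) stop("no grid density achieves full connectivity")
  d
}

#' Density window
#'
#' @param d_lo,d_hi window endpoints, `0 < d_lo < d_hi <= 1`.
#' @export
density_window <- function(d_lo, d_hi) {
  if (!(d_lo > 0 && d_lo < d_hi && d_hi <= 1))
    stop("invalid density window [", d_lo, ", ", d_hi, "]")
  structure(list(d_lo = d_lo, d_hi = d_hi), class = "density_window")
}

#' Density range of small-world organization
#'
#' The analysis window runs from the minimum connection density to the last
#' density with small-world organization (sigma > 1), capped at a maximum
#' density of 0.5 (denser networks approach randomness and their metrics are
#' dominated by spurious edges).
#'
#' @param sigma matrix of small-worldness values, subjects x densities.
#' @param grid density grid matching `ncol(sigma)`.
#' @param d_min lower end (typically the minimum connection density).
#' @param d_max cap (default 0.5).
#' @param rule `"mean"` requires group-mean sigma > 1; `"all"` requires every
#'   subject's sigma > 1.
#' @return a [density_window].
#' @export
small_world_density_range <- function(sigma, grid, d_min, d_max = 0.5,
                                      rule = c("mean", "all")) {
  rule <- match.arg(rule)
  sigma <- rbind(sigma)
  stopifnot(ncol(sigma) == length(grid))
  ok <- if (rule == "mean") colMeans(sigma) > 1 else
    apply(sigma, 2, function(col) all(col > 1))
  usable <- ok & grid >= d_min - 1e-9
  if (!any(usable))
    stop("no small-world regime: sigma never exceeds 1 at density >= ", d_min)
  d_hi <- min(max(grid[usable]), d_max)
  density_window(d_min, d_hi)
}

#' First crossover density of two group-mean curves
#'
#' Locates the first grid density at which the sign of (mean A - mean B)
#' changes; this splits the density range into two AUC windows. Returns
#' `NULL` when the curves never cross (caller falls back to full-range AUC
#' only).
#'
#' @param mean_a,mean_b group-mean metric curves on a common grid.
#' @param grid the density grid.
#' @export
find_crossover <- function(mean_a, mean_b, grid) {
  stopifnot(length(mean_a) == length(grid), length(mean_b) == length(grid))
  s <- sign(mean_a - mean_b)
  nz <- which(s != 0)
  if (!length(nz)) return(NULL)
  first <- s[nz[1]]
  flip <- nz[s[nz] != first]
  if (!length(flip)) return(NULL)
  grid[flip[1]]
}

#' Area under a metric curve over a density window
#'
#' Trapezoidal integral of a metric over density, the threshold-free summary
#' used for group comparison. Window endpoints must be grid points.
#'
#' @param values metric values, one per grid density.
#' @param grid density grid.
#' @param window a [density_window] (or a length-2 numeric `c(lo, hi)`).
#' @export
auc_over_window <- function(values, grid, window) {
  if (is.numeric(window) && length(window) == 2)
    window <- density_window(window[1], window[2])
  stopifnot(inherits(window, "density_window"),
            length(values) == length(grid))
  i_lo <- which(abs(grid - window$d_lo) < 1e-9)
  i_hi <- which(abs(grid - window$d_hi) < 1e-9)
  if (!length(i_lo) || !length(i_hi))
    stop("window endpoints must lie on the density grid")
  idx <- i_lo:i_hi
  x <- grid[idx]; y <- values[idx]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
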