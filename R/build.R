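#' Build a functional connectome from region time series
#'
#' Pairwise Pearson correlations between region time series are Fisher
#' r-to-z transformed (atanh); negative edges are zeroed, since networks of
#' negative correlations behave differently from positive-correlation
#' networks and the two should not be mixed. Correlations are clipped to
#' |r| <= 1 - 1e-7 before the transform so duplicated signals cannot
#' produce infinite weights.
#'
#' @param ts numeric matrix of BOLD-like signals, regions x timepoints
#'   (N x T, T >= 3).
#' @param labels optional region labels (defaults to rownames).
#' @return a weighted functional [connectome].
#' @export
build_functional_connectome <- function(ts, labels = NULL) {
  if (!is.matrix(ts) || !is.numeric(ts)) stop("time series must be a numeric matrix")
  if (anyNA(ts)) stop("time series contain NA")
  if (ncol(ts) < 3) stop("need at least 3 timepoints, got ", ncol(ts))
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(rownames(ts))) rownames(ts)[bad] else bad
    stop("zero-variance region(s), correlation undefined: ",
         paste(nm, collapse = ", "))
  }
  r <- stats::cor(t(ts))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[z < 0] <- 0
  diag(z) <- 0
  if (is.null(labels)) labels <- rownames(ts)
  connectome(z, labels, modality = "functional", weighted = TRUE)
}

#' Build a structural connectome from streamline counts and FA
#'
#' A region pair is connected when at least `min_streamlines` tractography
#' streamlines join it (the count threshold removes likely false-positive
#' streamlines); each surviving edge is weighted by the mean fractional
#' anisotropy (FA) of its streamlines. Weights are then scaled to the range
#' 0 to 1 by dividing by the maximum surviving weight, so zero still means
#' "no edge" rather than "weakest edge".
#'
#' @param counts integer-valued symmetric N x N streamline-count matrix.
#' @param fa symmetric N x N matrix of mean FA per pair, values in `[0, 1]`,
#'   defined (> 0) wherever `counts > 0`.
#' @param min_streamlines minimum streamline count for a valid edge
#'   (inclusive; default 3).
#' @param scale `"subject"` divides by this subject's maximum surviving
#'   weight; `"none"` keeps raw FA weights (useful when scaling across a
#'   cohort externally).
#' @param labels optional region labels.
#' @return a weighted structural [connectome].
#' @export
build_structural_connectome <- function(counts, fa, min_streamlines = 3,
                                        scale = c("subject", "none"),
                                        labels = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(counts) || !is.matrix(fa)) stop("counts and fa must be matrices")
  if (!all(dim(counts) == dim(fa))) stop("counts and fa dimensions differ")
  if (anyNA(counts) || anyNA(fa)) stop("NA entries in streamline table")
  if (any(counts < 0)) stop("negative streamline counts")
  if (any(fa < 0 | fa > 1)) stop("FA values must lie in [0, 1]")
  if (max(abs(counts - t(counts))) > 0) stop("streamline counts not symmetric")
  w <- ifelse(counts >= min_streamlines, fa, 0)
  diag(w) <- 0
  if (all(w == 0))
    stop("empty structural network: no edge reaches ", min_streamlines,
         " streamlines")
  if (any(w[counts >= min_streamlines & upper.tri(w)] == 0))
    warning("surviving edge(s) with FA = 0; check the FA table")
  if (scale == "subject") w <- w / max(w)
  if (is.null(labels)) labels <- rownames(counts)
  connectome(w, labels, modality = "structural", weighted = TRUE)
}
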