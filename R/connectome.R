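#' Connectome object
#'
#' A connectome is an undirected, weighted brain network: an N x N symmetric,
#' nonnegative matrix with a zero diagonal, one row/column per brain region.
#' Edge count E is the number of nonzero upper-triangle entries and density
#' D = E / (N(N-1)/2) is the fraction of possible connections present.
#'
#' @param matrix numeric N x N matrix; symmetric within `tol`, nonnegative,
#'   zero diagonal. Small asymmetries (<= `tol`) are averaged out.
#' @param labels character vector of N region names (defaults to `"R1"..."RN"`).
#' @param modality `"functional"` or `"structural"`.
#' @param weighted logical; `FALSE` marks a binarized network.
#' @param tol asymmetry tolerance; larger asymmetry is an error, not silently
#'   fixed, so transposed or truncated files are caught.
#' @return An object of class `connectome` with elements `matrix`, `labels`,
#'   `modality`, `weighted`, `n_nodes`, `n_edges`, `density`.
#' @export
connectome <- function(matrix, labels = NULL, modality = "structural",
                       weighted = TRUE, tol = 1e-8) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("connectome matrix must be a numeric matrix")
  n <- nrow(matrix)
  if (ncol(matrix) != n)
    stop("connectome matrix must be square, got ", n, " x ", ncol(matrix))
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop("non-numeric entry (NA/NaN/Inf) in connectome matrix")
  asym <- max(abs(matrix - t(matrix)))
  if (asym > tol)
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.1g", asym, tol))
  matrix <- (matrix + t(matrix)) / 2
  diag(matrix) <- 0
  if (any(matrix < 0))
    stop("negative edge weights are not allowed in a connectome")
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  if (length(labels) != n)
    stop("label count (", length(labels), ") does not match matrix size (", n, ")")
  modality <- match.arg(modality, c("functional", "structural"))
  dimnames(matrix) <- list(labels, labels)
  e <- sum(matrix[upper.tri(matrix)] != 0)
  structure(list(
    matrix   = matrix,
    labels   = as.character(labels),
    modality = modality,
    weighted = isTRUE(weighted),
    n_nodes  = n,
    n_edges  = e,
    density  = e / (n * (n - 1) / 2)
  ), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s, %s: %d nodes, %d edges, density %.3f\n",
              x$modality, if (x$weighted) "weighted" else "binary",
              x$n_nodes, x$n_edges, x$density))
  invisible(x)
}

#' Read a connectome matrix from a delimited text file
#'
#' The file is a square numeric table with no header, comma- or tab-delimited
#' (auto-detected). Region labels come from an optional sidecar file with one
#' label per line, in matrix order.
#'
#' @param path path to the matrix file.
#' @param labels_path optional path to the label sidecar.
#' @inheritParams connectome
#' @return a validated [connectome].
#' @export
read_connectome <- function(path, labels_path = NULL,
                            modality = "structural", weighted = TRUE) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  mat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  labels <- NULL
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
    labels <- readLines(labels_path)
    labels <- labels[nzchar(labels)]
  }
  connectome(mat, labels, modality = modality, weighted = weighted)
}

#' Write a connectome matrix to a delimited text file
#'
#' Writes the weight matrix at full double precision (round-trips to 1e-12)
#' as tab-separated values, plus an optional label sidecar.
#'
#' @param conn a [connectome].
#' @param path output matrix path.
#' @param labels_path optional sidecar path for region labels.
#' @export
write_connectome <- function(conn, path, labels_path = NULL) {
  stopifnot(inherits(conn, "connectome"))
  mat <- format(conn$matrix, digits = 17, trim = TRUE, scientific = TRUE)
  writeLines(apply(mat, 1, paste, collapse = "\t"), path)
  if (!is.null(labels_path)) writeLines(conn$labels, labels_path)
  invisible(path)
}

#' Load a cohort manifest
#'
#' A manifest is a YAML file assigning subjects to the two study groups and
#' pointing at their per-modality data files:
#' ```yaml
#' subjects:
#'   - id: tg1
#'     group: TG
#'     functional: ts_tg1.tsv
#'     structural_counts: counts_tg1.tsv
#'     structural_fa: fa_tg1.tsv
#' ```
#' Paths are resolved relative to the manifest's directory.
#'
#' @param path manifest file path.
#' @param check_files warn about referenced files that do not exist.
#' @return a list of class `cohort_manifest` with `subjects` (data.frame:
#'   id, group, plus one column per path key) and `group_sizes`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$subjects) || !length(raw$subjects))
    stop("manifest has no subjects")
  rows <- lapply(raw$subjects, function(s) {
    if (is.null(s$id) || is.null(s$group))
      stop("every manifest subject needs 'id' and 'group'")
    as.data.frame(s, stringsAsFactors = FALSE)
  })
  subjects <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (anyDuplicated(subjects$id))
    stop("duplicate subject id(s): ",
         paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", "))
  groups <- unique(subjects$group)
  if (length(groups) != 2L)
    stop("manifest must define exactly two groups, found: ",
         paste(groups, collapse = ", "))
  base <- dirname(normalizePath(path))
  path_cols <- setdiff(names(subjects), c("id", "group"))
  for (col in path_cols) {
    abs <- ifelse(grepl("^(/|[A-Za-z]:)", subjects[[col]]),
                  subjects[[col]], file.path(base, subjects[[col]]))
    subjects[[col]] <- abs
    if (check_files) {
      missing <- abs[!file.exists(abs)]
      if (length(missing))
        warning("manifest references missing file(s): ",
                paste(missing, collapse = ", "))
    }
  }
  structure(list(
    subjects    = subjects,
    groups      = groups,
    group_sizes = table(factor(subjects$group, levels = groups))
  ), class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest> %d subjects: %s\n", nrow(x$subjects),
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  invisible(x)
}

## shared helpers -----------------------------------------------------------

# upper-triangle index pairs of an n x n matrix, column-major order
ut_pairs <- function(n) {
  which(upper.tri(diag(n)), arr.ind = TRUE)
}

# extract upper-triangle vector
ut_vec <- function(mat) mat[upper.tri(mat)]

# rebuild a symmetric matrix (zero diagonal) from an upper-triangle vector
sym_from_ut <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}
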