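#' Pearson functional connectivity with Fisher z transform
#'
#' Computes the full pairwise Pearson correlation matrix between ROI time
#' series and maps it to Fisher z scores (atanh). The diagonal is set to 0
#' by convention and is never consumed downstream. Off-diagonal
#' correlations of magnitude 1 (possible in degenerate fixtures) are
#' clamped to +/-(1 - 1e-12) with a warning before the transform so the
#' result stays finite.
#'
#' @param ts numeric matrix of BOLD samples, timepoints x ROIs (>= 2 rows,
#'   >= 2 columns, no missing values). Column names, if present, name the
#'   nodes in error messages.
#' @return Symmetric numeric matrix (ROIs x ROIs) of Fisher-z edge weights
#'   with zero diagonal.
#' @export
#' @examples
#' ts <- matrix(rnorm(40), 10, 4)
#' z <- compute_fc_matrix(ts)
#' all.equal(z, t(z))
compute_fc_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 2L) stop("need at least 2 timepoints")
  if (ncol(ts) < 2L) stop("need at least 2 nodes")
  if (anyNA(ts)) stop("time series contain missing values")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(ts))) colnames(ts)[bad] else bad
    stop("zero-variance time series for node(s): ", paste(nm, collapse = ", "))
  }
  r <- stats::cor(ts)
  diag(r) <- 0
  if (any(abs(r) >= 1)) {
    warning("perfectly (anti)correlated node pair(s); correlation clamped to ",
            "+/-(1 - 1e-12) before the Fisher transform")
    r[r >= 1] <- 1 - 1e-12
    r[r <= -1] <- -(1 - 1e-12)
  }
  z <- atanh(r)
  diag(z) <- 0
  dimnames(z) <- NULL
  z
}

#' Average Fisher-z connectivity matrices across runs
#'
#' Element-wise arithmetic mean of per-run Fisher-z matrices. Full-size
#' acquisitions have four runs; fewer are accepted (with a warning below
#' four) so small fixtures work.
#'
#' @param mats list of square numeric matrices of identical dimension.
#' @param expected_runs runs expected per subject (default 4); fewer
#'   triggers a warning, not an error.
#' @return The element-wise mean matrix.
#' @export
average_runs <- function(mats, expected_runs = 4L) {
  if (!is.list(mats) || length(mats) == 0L)
    stop("'mats' must be a non-empty list of connectivity matrices")
  dims <- vapply(mats, function(m) dim(as.matrix(m)), integer(2))
  if (length(unique(dims[1, ])) != 1L || any(dims[1, ] != dims[2, ]))
    stop("all matrices must be square with the same node count")
  if (length(mats) < expected_runs)
    warning("averaging ", length(mats), " run(s); ", expected_runs,
            " expected for a full acquisition")
  Reduce(`+`, lapply(mats, as.matrix)) / length(mats)
}

#' Number of unique edges for an R-node parcellation
#'
#' @param n_nodes node count R.
#' @return R(R-1)/2.
#' @export
#' @examples
#' n_edges(268)  # 35778
n_edges <- function(n_nodes) {
  r <- as.integer(n_nodes)
  (r * (r - 1L)) %/% 2L
}

#' Vectorize the strict lower triangle of a connectivity matrix
#'
#' Extracts the strictly-lower-triangular entries (i > j, excluding the
#' diagonal) in row-major order over node pairs: (2,1), (3,1), (3,2),
#' (4,1), ... This ordering is fixed package-wide; [edge_to_nodes()] and
#' [nodes_to_edge()] convert between edge indices and node pairs.
#'
#' @param mat symmetric numeric matrix.
#' @param tol symmetry tolerance (default 1e-10).
#' @return Numeric vector of length R(R-1)/2.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' vectorize_lower_triangle(m)  # 1 2 3
vectorize_lower_triangle <- function(mat, tol = 1e-10) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("matrix must be square")
  if (max(abs(mat - t(mat))) > tol)
    stop("matrix is asymmetric beyond tolerance ", tol)
  # column-major traversal of the strict upper triangle of t(mat) yields the
  # lower triangle of mat in row-major (i > j) pair order
  tm <- t(mat)
  tm[upper.tri(tm)]
}

#' Rebuild a symmetric connectivity matrix from an edge vector
#'
#' Inverse of [vectorize_lower_triangle()]: places the edge weights back in
#' the lower and upper triangles and zeros the diagonal.
#'
#' @param edges numeric vector of length R(R-1)/2 in the package edge order.
#' @param n_nodes node count R; inferred from the vector length if omitted.
#' @return Symmetric R x R matrix with zero diagonal.
#' @export
devectorize_edges <- function(edges, n_nodes = NULL) {
  m <- length(edges)
  if (is.null(n_nodes)) {
    n_nodes <- (1 + sqrt(1 + 8 * m)) / 2
    if (abs(n_nodes - round(n_nodes)) > 1e-8)
      stop("edge vector length ", m, " is not R(R-1)/2 for any integer R")
    n_nodes <- as.integer(round(n_nodes))
  }
  if (m != n_edges(n_nodes))
    stop("edge vector length ", m, " does not match node count ", n_nodes)
  out <- matrix(0, n_nodes, n_nodes)
  out[upper.tri(out)] <- edges
  out <- t(out)
  out[upper.tri(out)] <- edges
  t(out)
}

#' Map an edge index to its node pair
#'
#' Edge k (1-based) in the package ordering corresponds to the node pair
#' (i, j) with i > j, enumerated row-major: (2,1), (3,1), (3,2), ...
#'
#' @param k integer edge index (vectorized), 1 <= k <= R(R-1)/2.
#' @param n_nodes node count R.
#' @return Integer matrix with columns `i`, `j` (i > j), one row per k.
#' @export
#' @examples
#' edge_to_nodes(1, 3)   # i = 2, j = 1
#' edge_to_nodes(45, 10) # i = 10, j = 9
edge_to_nodes <- function(k, n_nodes) {
  k <- as.integer(k)
  if (any(k < 1L) || any(k > n_edges(n_nodes)))
    stop("edge index out of range 1..", n_edges(n_nodes))
  k0 <- k - 1L
  i0 <- floor((1 + sqrt(1 + 8 * k0)) / 2)
  # guard against floating-point at triangular-number boundaries
  i0 <- ifelse(i0 * (i0 - 1) / 2 > k0, i0 - 1, i0)
  i0 <- ifelse((i0 + 1) * i0 / 2 <= k0, i0 + 1, i0)
  j0 <- k0 - i0 * (i0 - 1) / 2
  cbind(i = as.integer(i0) + 1L, j = as.integer(j0) + 1L)
}

#' Map a node pair to its edge index
#'
#' @param i,j node indices (order-insensitive; i != j), 1-based.
#' @param n_nodes node count R.
#' @return Integer edge index in the package ordering.
#' @export
nodes_to_edge <- function(i, j, n_nodes) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(i == j)) stop("self-edges do not exist (i == j)")
  if (any(i < 1L | i > n_nodes | j < 1L | j > n_nodes))
    stop("node index out of range 1..", n_nodes)
  hi <- pmax(i, j) - 1L
  lo <- pmin(i, j) - 1L
  as.integer(hi * (hi - 1L) / 2 + lo + 1L)
}

#' Read a ROI time-series table
#'
#' One file per subject-run: delimited text, one row per timepoint, one
#' column per node, with a header row of node identifiers.
#'
#' @param path file path (TSV/CSV, separator auto-detected).
#' @return Numeric matrix timepoints x nodes.
#' @export
read_timeseries <- function(path) {
  tab <- read_delim_auto(path)
  as.matrix(tab)
}

#' Read a precomputed square connectivity matrix
#'
#' @param path delimited text file holding an R x R matrix (no header).
#' @return Numeric R x R matrix.
#' @export
read_fc_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("connectivity matrix file is not square")
  m
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
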