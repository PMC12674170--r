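#' Tally edge selection across bootstrap models
#'
#' An edge counts once per bootstrap iteration iff it was selected in BOTH
#' fold directions of that iteration (train -> test and test -> train):
#' the fold-consistency rule for leave-one-group-out cross-validation.
#'
#' @param selected per-iteration selections: either the `selected` field of
#'   a [run_logocv_bootstrap()] result, or a list of lists with components
#'   `train_to_test` and `test_to_train` (integer edge-index vectors).
#' @param n_edges total edge count of the parcellation.
#' @return list of class `edge_consensus`: `counts` (integer vector of
#'   length `n_edges`), `B` (number of models).
#' @export
tally_edge_selection <- function(selected, n_edges) {
  if (inherits(selected, "prediction_result")) {
    n_edges <- selected$n_edges
    selected <- selected$selected
  }
  if (length(selected) == 0L) stop("no iterations to tally")
  counts <- integer(n_edges)
  for (it in selected) {
    if (is.null(it$train_to_test) || is.null(it$test_to_train))
      stop("each iteration needs both fold directions' selections")
    both <- intersect(it$train_to_test, it$test_to_train)
    counts[both] <- counts[both] + 1L
  }
  structure(list(counts = counts, B = length(selected)),
            class = "edge_consensus")
}

#' Threshold a consensus tally
#'
#' Keeps the edges selected in strictly more than `fraction` of the B
#' models — e.g. at `fraction = 0.5` with B = 1000, a count of 500 is
#' excluded and 501 included (the "more than 50%" rule, strict).
#'
#' @param consensus an `edge_consensus`.
#' @param fraction threshold fraction in (0, 1), default 0.5.
#' @return Integer vector of retained edge indices.
#' @export
threshold_consensus <- function(consensus, fraction = 0.5) {
  stopifnot(inherits(consensus, "edge_consensus"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  which(consensus$counts > fraction * consensus$B)
}

#' Node connectivity strength
#'
#' The strength of a node is the number of retained edges incident to it
#' (unweighted), or the sum of |weights| of incident edges when `weights`
#' is supplied.
#'
#' @param edge_set integer vector of edge indices.
#' @param n_nodes node count R.
#' @param weights optional numeric weights, one per edge in `edge_set`.
#' @return Numeric vector of length R.
#' @export
node_strength <- function(edge_set, n_nodes, weights = NULL) {
  strength <- numeric(n_nodes)
  if (length(edge_set) == 0L) return(strength)
  np <- edge_to_nodes(edge_set, n_nodes)
  w <- if (is.null(weights)) rep(1, length(edge_set)) else abs(weights)
  if (length(w) != length(edge_set))
    stop("one weight per edge required")
  for (e in seq_len(nrow(np))) {
    strength[np[e, 1L]] <- strength[np[e, 1L]] + w[e]
    strength[np[e, 2L]] <- strength[np[e, 2L]] + w[e]
  }
  strength
}

#' Top-k nodes by connectivity strength
#'
#' Ranks nodes by descending strength; ties are broken by ascending node
#' id, for determinism. Network labels and MNI coordinates are attached
#' when an atlas is given.
#'
#' @param strengths per-node strength vector.
#' @param k how many nodes (default 5).
#' @param atlas optional `network_atlas`.
#' @return data.frame with columns `node`, `strength`, and (with an atlas)
#'   `network` plus `x`, `y`, `z` when coordinates exist.
#' @export
top_k_nodes <- function(strengths, k = 5L, atlas = NULL) {
  r <- length(strengths)
  if (k > r) stop("k exceeds the node count")
  ord <- order(-strengths, seq_len(r))[seq_len(k)]
  out <- data.frame(node = ord, strength = strengths[ord])
  if (!is.null(atlas)) {
    stopifnot(atlas$node_count == r)
    out$network <- atlas$node_labels[ord]
    if (!is.null(atlas$node_coords)) {
      out$x <- atlas$node_coords[ord, 1]
      out$y <- atlas$node_coords[ord, 2]
      out$z <- atlas$node_coords[ord, 3]
    }
  }
  out
}

#' Network-pair tally of an edge set
#'
#' Counts retained edges by the networks of their two endpoints: a 10 x 10
#' (or however many networks the atlas has) upper-triangular table whose
#' diagonal holds within-network counts. The table total equals the edge
#' set size.
#'
#' @param edge_set integer vector of edge indices.
#' @param atlas a `network_atlas`.
#' @return Integer matrix, networks x networks (upper triangle + diagonal
#'   populated; rows/columns in atlas label order).
#' @export
network_tally <- function(edge_set, atlas) {
  stopifnot(inherits(atlas, "network_atlas"))
  nets <- unique(atlas$node_labels)
  tal <- matrix(0L, length(nets), length(nets),
                dimnames = list(nets, nets))
  if (length(edge_set) == 0L) return(tal)
  np <- edge_to_nodes(edge_set, atlas$node_count)
  a <- match(atlas$node_labels[np[, 1L]], nets)
  b <- match(atlas$node_labels[np[, 2L]], nets)
  lo <- pmin(a, b); hi <- pmax(a, b)
  for (e in seq_along(lo))
    tal[lo[e], hi[e]] <- tal[lo[e], hi[e]] + 1L
  tal
}

#' Export a consensus edge set as a delimited table
#'
#' @param edge_set integer vector of edge indices.
#' @param consensus the `edge_consensus` the set came from.
#' @param atlas a `network_atlas`.
#' @param path optional output path (TSV); when NULL the table is returned
#'   only.
#' @return data.frame with columns `edge`, `node_i`, `node_j`,
#'   `network_i`, `network_j`, `count`.
#' @export
consensus_edge_table <- function(edge_set, consensus, atlas, path = NULL) {
  np <- edge_to_nodes(edge_set, atlas$node_count)
  tab <- data.frame(edge = edge_set,
                    node_i = np[, 1L], node_j = np[, 2L],
                    network_i = atlas$node_labels[np[, 1L]],
                    network_j = atlas$node_labels[np[, 2L]],
                    count = consensus$counts[edge_set])
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  tab
}
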