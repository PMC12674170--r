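#' Canonical resting-state network names and node counts
#'
#' The ten canonical functional networks used throughout the package, with
#' the node counts of the 268-node parcellation: medial frontal (MFN, 29),
#' frontoparietal (FPN, 28), default mode (DMN, 18), motor (MOT, 49),
#' visual I (VISI, 18), visual II (VISII, 9), visual association (VAN, 18),
#' limbic (LMB, 30), basal ganglia (BG, 29) and cerebellum (CRB, 40).
#'
#' @return Named integer vector of node counts (names are network labels).
#' @export
#' @examples
#' sum(canonical_network_sizes())  # 268
canonical_network_sizes <- function() {
  c(MFN = 29L, FPN = 28L, DMN = 18L, MOT = 49L, VISI = 18L,
    VISII = 9L, VAN = 18L, LMB = 30L, BG = 29L, CRB = 40L)
}

#' Construct a network atlas
#'
#' An atlas maps each node of the parcellation to exactly one functional
#' network and, optionally, to MNI coordinates (mm).
#'
#' @param node_labels character vector, one network label per node.
#' @param node_coords optional numeric matrix (nodes x 3) of MNI coordinates.
#' @return An object of class `network_atlas` with fields `node_labels`,
#'   `node_coords` and `node_count`.
#' @export
network_atlas <- function(node_labels, node_coords = NULL) {
  node_labels <- as.character(node_labels)
  r <- length(node_labels)
  if (r < 2L) stop("an atlas needs at least 2 nodes")
  if (anyNA(node_labels)) stop("every node must carry a network label")
  if (!is.null(node_coords)) {
    node_coords <- as.matrix(node_coords)
    if (nrow(node_coords) != r || ncol(node_coords) != 3L)
      stop("node_coords must be a nodes x 3 matrix of MNI coordinates")
  }
  structure(list(node_labels = node_labels, node_coords = node_coords,
                 node_count = r),
            class = "network_atlas")
}

#' @export
print.network_atlas <- function(x, ...) {
  cat("network_atlas:", x$node_count, "nodes,",
      length(unique(x$node_labels)), "networks\n")
  print(table(factor(x$node_labels, levels = unique(x$node_labels))))
  invisible(x)
}

#' The canonical 268-node atlas
#'
#' Builds a 268-node atlas with the canonical per-network node counts (see
#' [canonical_network_sizes()]). The published parcellation's node-to-network
#' assignment is not redistributable, so nodes are assigned in contiguous
#' blocks in the canonical order: this synthetic ordering preserves the
#' network sizes (which is all the pipeline's network-level operations
#' depend on), not the anatomical identity of individual nodes.
#'
#' @return A `network_atlas` with 268 nodes.
#' @export
canonical_atlas <- function() {
  sizes <- canonical_network_sizes()
  network_atlas(rep(names(sizes), times = sizes))
}

#' A proportionally scaled-down atlas
#'
#' Allocates `n_nodes` nodes to the ten canonical networks proportionally to
#' the canonical 268-node counts, using largest-remainder rounding so the
#' counts sum exactly to `n_nodes`. Used for desk-scale synthetic cohorts.
#'
#' @param n_nodes total node count (>= 10).
#' @return A `network_atlas`.
#' @export
#' @examples
#' table(scaled_atlas(40)$node_labels)
scaled_atlas <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes == 268L) return(canonical_atlas())
  if (n_nodes < 10L) stop("need at least one node per network (n_nodes >= 10)")
  sizes <- canonical_network_sizes()
  quota <- sizes / sum(sizes) * n_nodes
  base <- floor(quota)
  rem <- n_nodes - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  network_atlas(rep(names(sizes), times = base))
}

#' Read an atlas from a delimited table
#'
#' Expects columns `node_id`, `network` and optionally `x`, `y`, `z`
#' (MNI mm). Rows are ordered by `node_id`.
#'
#' @param path file path (TSV/CSV, separator auto-detected from extension).
#' @return A `network_atlas`.
#' @export
read_atlas <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("node_id", "network")
  if (!all(need %in% names(tab)))
    stop("atlas table must contain columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$node_id), , drop = FALSE]
  coords <- NULL
  if (all(c("x", "y", "z") %in% names(tab)))
    coords <- as.matrix(tab[, c("x", "y", "z")])
  network_atlas(tab$network, coords)
}

#' Write an atlas to a delimited table
#'
#' @param atlas a `network_atlas`.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "network_atlas"))
  tab <- data.frame(node_id = seq_len(atlas$node_count),
                    network = atlas$node_labels)
  if (!is.null(atlas$node_coords)) {
    tab$x <- atlas$node_coords[, 1]
    tab$y <- atlas$node_coords[, 2]
    tab$z <- atlas$node_coords[, 3]
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

match_network <- function(atlas, network) {
  valid <- unique(atlas$node_labels)
  if (!network %in% valid)
    stop("unknown network '", network, "'; valid networks: ",
         paste(valid, collapse = ", "))
  which(atlas$node_labels == network)
}

#' Edge indices of all within-network connections
#'
#' Returns the indices (in the lower-triangle edge ordering, see
#' [vectorize_lower_triangle()]) of every edge whose two endpoints both
#' belong to the given network. A network with m nodes contributes
#' m(m-1)/2 intra-network edges.
#'
#' @param atlas a `network_atlas`.
#' @param network a network label present in the atlas.
#' @return Integer vector of edge indices (possibly empty).
#' @export
#' @examples
#' length(intra_network_edge_indices(canonical_atlas(), "DMN"))  # 153
intra_network_edge_indices <- function(atlas, network) {
  nodes <- match_network(atlas, network)
  m <- length(nodes)
  if (m < 2L) return(integer(0))
  pr <- utils::combn(nodes, 2L)
  sort(nodes_to_edge(pr[2L, ], pr[1L, ], atlas$node_count))
}
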