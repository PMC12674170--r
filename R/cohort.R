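#' Construct a twin cohort
#'
#' A cohort couples a roster of twin subjects with their vectorized FC edge
#' weights. Every pair id must occur exactly twice, co-twins must share
#' zygosity, and the edge matrix must have one row per subject.
#'
#' @param roster data.frame with columns `subject_id`, `pair_id`,
#'   `zygosity` ("MZ"/"DZ"), `age`, `gender` (binary 0/1), `g_raw` and
#'   optionally `g_adjusted`.
#' @param edges numeric matrix, subjects x edges, rows in roster order
#'   (row names, if present, must match `subject_id`).
#' @param n_nodes node count R consistent with `ncol(edges) == R(R-1)/2`;
#'   inferred if omitted.
#' @return An object of class `twin_cohort` with fields `roster`, `edges`,
#'   `n_nodes`.
#' @export
twin_cohort <- function(roster, edges, n_nodes = NULL) {
  need <- c("subject_id", "pair_id", "zygosity", "age", "gender", "g_raw")
  if (!all(need %in% names(roster)))
    stop("roster must contain columns: ", paste(need, collapse = ", "))
  roster$subject_id <- as.character(roster$subject_id)
  roster$pair_id <- as.character(roster$pair_id)
  if (anyDuplicated(roster$subject_id))
    stop("duplicate subject ids in roster")
  counts <- table(roster$pair_id)
  if (any(counts != 2L))
    stop("every pair_id must occur exactly twice; offending: ",
         paste(names(counts)[counts != 2L], collapse = ", "))
  zy <- tapply(roster$zygosity, roster$pair_id,
               function(z) length(unique(z)))
  if (any(zy != 1L)) stop("co-twins must share zygosity")
  if (!all(roster$zygosity %in% c("MZ", "DZ")))
    stop("zygosity must be 'MZ' or 'DZ'")
  edges <- as.matrix(edges)
  if (nrow(edges) != nrow(roster))
    stop("edge matrix must have one row per roster subject")
  if (!is.null(rownames(edges)) &&
      !identical(rownames(edges), roster$subject_id))
    stop("edge matrix row names disagree with roster subject ids")
  if (is.null(n_nodes)) {
    n_nodes <- (1 + sqrt(1 + 8 * ncol(edges))) / 2
    if (abs(n_nodes - round(n_nodes)) > 1e-8)
      stop("edge count ", ncol(edges), " is not R(R-1)/2 for any integer R")
    n_nodes <- as.integer(round(n_nodes))
  }
  if (ncol(edges) != n_edges(n_nodes))
    stop("edge count does not match node count")
  rownames(edges) <- roster$subject_id
  if (is.null(roster$g_adjusted)) roster$g_adjusted <- NA_real_
  structure(list(roster = roster, edges = edges, n_nodes = n_nodes),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  nz <- table(x$roster$zygosity) / 2
  cat("twin_cohort:", nrow(x$roster), "subjects (",
      paste(names(nz), nz, "pairs", collapse = ", "), "),",
      x$n_nodes, "nodes /", ncol(x$edges), "edges\n")
  invisible(x)
}

#' Subset a cohort by zygosity
#'
#' @param cohort a `twin_cohort`.
#' @param zygosity "MZ", "DZ" or NULL (no subsetting).
#' @return A `twin_cohort` restricted to pairs of that zygosity.
#' @export
cohort_subset <- function(cohort, zygosity = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (is.null(zygosity)) return(cohort)
  keep <- cohort$roster$zygosity == zygosity
  if (!any(keep)) stop("no ", zygosity, " pairs in cohort")
  out <- cohort
  out$roster <- cohort$roster[keep, , drop = FALSE]
  out$edges <- cohort$edges[keep, , drop = FALSE]
  rownames(out$roster) <- NULL
  out
}

#' Combine cohorts (e.g. an MZ and a DZ cohort) into one
#'
#' @param ... `twin_cohort` objects sharing the same node count with
#'   disjoint subject and pair ids.
#' @return A single `twin_cohort`.
#' @export
combine_cohorts <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "twin_cohort")))
  r <- unique(vapply(parts, `[[`, 1L, "n_nodes"))
  if (length(r) != 1L) stop("cohorts must share the node count")
  roster <- do.call(rbind, lapply(parts, `[[`, "roster"))
  edges <- do.call(rbind, lapply(parts, `[[`, "edges"))
  twin_cohort(roster, edges, r)
}

#' Pair index of a cohort
#'
#' @param cohort a `twin_cohort`.
#' @return data.frame with one row per pair: `pair_id`, `zygosity`, and the
#'   roster row indices of the two members (`m1`, `m2`, in roster order).
#' @keywords internal
pair_index <- function(cohort) {
  ro <- cohort$roster
  ids <- unique(ro$pair_id)
  m1 <- match(ids, ro$pair_id)
  m2 <- nrow(ro) + 1L - match(ids, rev(ro$pair_id))
  data.frame(pair_id = ids, zygosity = ro$zygosity[m1],
             m1 = m1, m2 = m2, stringsAsFactors = FALSE)
}

#' Write / read a cohort as delimited text
#'
#' The roster goes to `<stem>_roster.tsv` and the edge matrix to
#' `<stem>_edges.tsv` (one row per subject, one column per edge).
#'
#' @param cohort a `twin_cohort`.
#' @param stem path stem for the two files.
#' @return `write_cohort`: the stem, invisibly. `read_cohort`: a
#'   `twin_cohort`.
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "twin_cohort"))
  utils::write.table(cohort$roster, paste0(stem, "_roster.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  edges <- as.data.frame(cohort$edges)
  names(edges) <- paste0("e", seq_len(ncol(edges)))
  utils::write.table(cbind(subject_id = cohort$roster$subject_id, edges),
                     paste0(stem, "_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(stem) {
  roster <- read_delim_auto(paste0(stem, "_roster.tsv"))
  etab <- read_delim_auto(paste0(stem, "_edges.tsv"))
  if (!identical(as.character(etab$subject_id),
                 as.character(roster$subject_id)))
    stop("edge file subject order disagrees with roster")
  edges <- as.matrix(etab[, -1, drop = FALSE])
  dimnames(edges) <- NULL
  twin_cohort(roster, edges)
}
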