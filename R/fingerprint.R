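#' Identify a subject's co-twin by connectivity fingerprinting
#'
#' Correlates the subject's (optionally masked) edge vector with every
#' other individual's in the candidate pool and returns the candidate with
#' the highest Pearson correlation. Ties break to the lowest subject id
#' (roster order), for determinism; candidates whose masked vector has
#' zero variance are excluded with a warning.
#'
#' @param subject_id the probe subject's id.
#' @param cohort a `twin_cohort`.
#' @param edge_mask optional integer vector of edge indices to restrict
#'   the fingerprint to (e.g. an intelligence-related consensus set);
#'   NULL uses all edges (whole-brain).
#' @param zygosity optional zygosity to restrict the candidate pool to.
#' @return The predicted co-twin's subject id (character).
#' @export
identify_cotwin <- function(subject_id, cohort, edge_mask = NULL,
                            zygosity = NULL) {
  sub <- cohort_subset(cohort, zygosity)
  ids <- sub$roster$subject_id
  probe <- match(subject_id, ids)
  if (is.na(probe)) stop("subject '", subject_id, "' not in cohort")
  E <- sub$edges
  if (!is.null(edge_mask)) E <- E[, edge_mask, drop = FALSE]
  if (ncol(E) < 2L) stop("fingerprinting needs at least 2 edges")
  pool <- setdiff(seq_along(ids), probe)
  if (length(pool) < 2L) stop("need at least 2 candidates")
  sds <- apply(E[pool, , drop = FALSE], 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding candidate(s) with zero-variance masked vectors: ",
            paste(ids[pool[sds == 0]], collapse = ", "))
    pool <- pool[sds > 0]
  }
  r <- drop(stats::cor(E[probe, ], t(E[pool, , drop = FALSE])))
  ids[pool[which.max(r)]]  # which.max takes the first (lowest id) on ties
}

#' Co-twin identification accuracy
#'
#' Runs [identify_cotwin()] symmetrically for both members of every pair
#' in the (optionally zygosity-restricted) cohort — each individual is one
#' identification attempt against all other individuals of that cohort —
#' and reports the percentage of attempts whose top match is the true
#' co-twin.
#'
#' @param cohort a `twin_cohort`.
#' @param zygosity "MZ", "DZ" or NULL.
#' @param edge_mask optional edge-index mask (see [identify_cotwin()]).
#' @return list of class `identification_result`: `accuracy` (percent),
#'   `n_attempted`, `n_correct`, `matches` (data.frame: subject, true
#'   co-twin, predicted, correct).
#' @export
identification_accuracy <- function(cohort, zygosity = NULL,
                                    edge_mask = NULL) {
  sub <- cohort_subset(cohort, zygosity)
  ids <- sub$roster$subject_id
  pid <- sub$roster$pair_id
  E <- sub$edges
  if (!is.null(edge_mask)) E <- E[, edge_mask, drop = FALSE]
  if (ncol(E) < 2L) stop("fingerprinting needs at least 2 edges")
  # full correlation matrix between subjects' edge vectors, computed once
  R <- suppressWarnings(stats::cor(t(E)))
  diag(R) <- -Inf
  R[is.na(R)] <- -Inf  # zero-variance vectors never win
  pred <- ids[apply(R, 1L, which.max)]
  truth <- vapply(seq_along(ids), function(i) {
    ids[pid == pid[i] & ids != ids[i]]
  }, character(1))
  correct <- pred == truth
  structure(list(accuracy = 100 * mean(correct),
                 n_attempted = length(ids), n_correct = sum(correct),
                 matches = data.frame(subject = ids, cotwin = truth,
                                      predicted = pred, correct = correct)),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("co-twin identification: %.1f%% (%d / %d attempts)\n",
              x$accuracy, x$n_correct, x$n_attempted))
  invisible(x)
}
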