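#' Within-pair absolute differences of G-score and FC
#'
#' For each twin pair, the absolute G-score difference |G_a - G_b| (a
#' scalar per pair) and the per-edge absolute FC difference vector
#' |edge_a - edge_b|. Larger G differences mean lower intelligence
#' similarity. Both are order-invariant in the pair members.
#'
#' @param cohort a `twin_cohort` with `g_adjusted` filled.
#' @param zygosity "MZ", "DZ" or NULL.
#' @return list of class `diff_dataset`: `pairs` (data.frame `pair_id`,
#'   `zygosity`, `d_g`), `d_edges` (pairs x edges matrix), `n_nodes`.
#' @export
pair_differences <- function(cohort, zygosity = NULL) {
  sub <- cohort_subset(cohort, zygosity)
  g <- sub$roster$g_adjusted
  if (anyNA(g)) stop("g_adjusted missing; call adjust_cohort_gscore() first")
  pi <- pair_index(sub)
  d_g <- abs(g[pi$m1] - g[pi$m2])
  d_edges <- abs(sub$edges[pi$m1, , drop = FALSE] -
                 sub$edges[pi$m2, , drop = FALSE])
  rownames(d_edges) <- pi$pair_id
  structure(list(pairs = data.frame(pair_id = pi$pair_id,
                                    zygosity = pi$zygosity, d_g = d_g),
                 d_edges = d_edges, n_nodes = sub$n_nodes),
            class = "diff_dataset")
}

# shared k-fold engine over a (pairs x edges) difference design
kfold_diff_engine <- function(d_edges, d_g, k, top_m, max_components,
                              inner_folds, fold) {
  n <- length(d_g)
  pred <- numeric(n)
  selected <- vector("list", k)
  for (kf in seq_len(k)) {
    tr <- fold != kf
    stats <- edge_f_statistics(d_edges[tr, , drop = FALSE], d_g[tr])
    m <- min(top_m, ncol(d_edges))
    sel <- order(stats$p, -stats$f)[seq_len(m)]
    model <- fit_plsr(d_edges[tr, sel, drop = FALSE], d_g[tr],
                      max_components, inner_folds)
    pred[!tr] <- predict_plsr(model, d_edges[!tr, sel, drop = FALSE])
    selected[[kf]] <- sort(sel)
  }
  r <- suppressWarnings(stats::cor(pred, d_g))
  list(r = if (is.na(r)) 0 else r, predictions = pred, selected = selected)
}

#' Predict within-pair G-score differences from FC differences
#'
#' k-fold cross-validated PLS regression of |dG| on |dFC|: within each
#' training split, edges are ranked by their univariate F statistic
#' against the training dG and the `top_m` most significant are kept; a
#' PLS model (inner-CV component selection, as in the cross-twin engine)
#' predicts the held-out fold. Out-of-fold predictions are pooled and
#' correlated with the observed dG (one r per cohort); significance comes
#' from refitting the full cross-validation on permuted dG.
#'
#' @param diffs a `diff_dataset` from [pair_differences()].
#' @param k folds (default 10).
#' @param top_m features retained per training split (default 400).
#' @param n_perm permutation iterations (5000 at full scale).
#' @param max_components PLS component-grid cap (default 100).
#' @param inner_folds inner CV folds for component selection (default 5).
#' @param seed RNG seed (fold assignment and permutations).
#' @param per_fold_r also report the mean of per-fold correlations
#'   (variant evaluation; the pooled r remains the primary statistic).
#' @return list of class `diff_prediction_result`: `r`, `predictions`,
#'   `observed`, `null_draws`, `p_perm`, `selected` (per fold),
#'   `per_fold_r` (optional), `params`.
#' @export
run_kfold_diff_prediction <- function(diffs, k = 10L, top_m = 400L,
                                      n_perm = 5000L,
                                      max_components = 100L,
                                      inner_folds = 5L, seed = 1L,
                                      per_fold_r = FALSE) {
  stopifnot(inherits(diffs, "diff_dataset"))
  d_g <- diffs$pairs$d_g
  n <- length(d_g)
  if (k > n) stop("k exceeds the pair count")
  if (k < 2L) stop("need at least 2 folds")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  main <- kfold_diff_engine(diffs$d_edges, d_g, k, top_m, max_components,
                            inner_folds, fold)
  pfr <- NULL
  if (per_fold_r) {
    pfr <- mean(vapply(seq_len(k), function(kf) {
      sel <- fold == kf
      v <- suppressWarnings(stats::cor(main$predictions[sel], d_g[sel]))
      if (is.na(v)) 0 else v
    }, numeric(1)))
  }
  null_draws <- numeric(n_perm)
  if (n_perm > 0L) {
    for (pp in seq_len(n_perm)) {
      null_draws[pp] <- kfold_diff_engine(diffs$d_edges, sample(d_g), k,
                                          top_m, max_components,
                                          inner_folds, fold)$r
    }
  }
  p_perm <- if (n_perm > 0L) permutation_pvalue(main$r, null_draws)
            else NA_real_
  structure(list(r = main$r, predictions = main$predictions,
                 observed = d_g, null_draws = null_draws, p_perm = p_perm,
                 selected = main$selected, per_fold_r = pfr,
                 params = list(k = k, top_m = top_m, n_perm = n_perm,
                               max_components = max_components,
                               inner_folds = inner_folds, seed = seed)),
            class = "diff_prediction_result")
}

#' @export
print.diff_prediction_result <- function(x, ...) {
  cat(sprintf("difference model: r = %.3f over %d pairs", x$r,
              length(x$observed)))
  if (!is.na(x$p_perm))
    cat(sprintf(", p_perm = %.4g (%d permutations)", x$p_perm,
                length(x$null_draws)))
  cat("\n")
  invisible(x)
}

#' Network-specific difference prediction
#'
#' The same k-fold difference pipeline restricted to the intra-network
#' edges of one functional network. When the network contributes fewer
#' than `top_m` edges, all of them enter the ranking (no cap).
#'
#' @param diffs a `diff_dataset`.
#' @param atlas a `network_atlas` matching the cohort's node count.
#' @param network a network label in the atlas (>= 2 nodes).
#' @inheritParams run_kfold_diff_prediction
#' @return A `diff_prediction_result` whose `params$network` names the
#'   network and `params$edge_indices` the columns used.
#' @export
network_specific_prediction <- function(diffs, atlas, network, k = 10L,
                                        top_m = 400L, n_perm = 5000L,
                                        max_components = 100L,
                                        inner_folds = 5L, seed = 1L) {
  stopifnot(inherits(diffs, "diff_dataset"))
  if (atlas$node_count != diffs$n_nodes)
    stop("atlas node count disagrees with the difference dataset")
  idx <- intra_network_edge_indices(atlas, network)
  if (length(idx) < 1L)
    stop("network '", network, "' has no intra-network edges ",
         "(fewer than 2 nodes)")
  sub <- diffs
  sub$d_edges <- diffs$d_edges[, idx, drop = FALSE]
  out <- run_kfold_diff_prediction(sub, k = k,
                                   top_m = min(top_m, length(idx)),
                                   n_perm = n_perm,
                                   max_components = max_components,
                                   inner_folds = inner_folds, seed = seed)
  out$selected <- lapply(out$selected, function(s) idx[s])
  out$params$network <- network
  out$params$edge_indices <- idx
  out
}
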