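#' Split twin pairs into training and testing groups
#'
#' Each pair contributes exactly one member to the training group and the
#' other to the testing group; the member is chosen by a fair coin from the
#' seeded generator. Co-twins therefore never share a group.
#'
#' @param cohort a `twin_cohort`.
#' @param zygosity "MZ", "DZ" or NULL (use all pairs).
#' @param seed integer RNG seed.
#' @return list of class `split_assignment`: `train_idx` and `test_idx`
#'   (roster row indices into the — possibly zygosity-subsetted — cohort),
#'   `train_ids`, `test_ids`, `pair_id`.
#' @export
split_pairs <- function(cohort, zygosity = NULL, seed = 1L) {
  sub <- cohort_subset(cohort, zygosity)
  pi <- pair_index(sub)
  if (nrow(pi) < 2L) stop("need at least 2 pairs to split")
  set.seed(seed)
  coin <- stats::rbinom(nrow(pi), 1L, 0.5)
  train <- ifelse(coin == 1L, pi$m1, pi$m2)
  test <- ifelse(coin == 1L, pi$m2, pi$m1)
  stopifnot(length(intersect(train, test)) == 0L)
  structure(list(train_idx = train, test_idx = test,
                 train_ids = sub$roster$subject_id[train],
                 test_ids = sub$roster$subject_id[test],
                 pair_id = pi$pair_id),
            class = "split_assignment")
}

#' Per-edge univariate F statistics against a response
#'
#' For each edge column, the F statistic of the simple linear regression of
#' y on that edge: F = r^2 (n-2) / (1 - r^2) with r the Pearson
#' correlation, referred to F(1, n-2). Constant columns get F = 0, p = 1
#' (never selected). This mirrors univariate F-test feature screening.
#'
#' @param X numeric matrix, subjects x edges.
#' @param y numeric response.
#' @return list with vectors `f`, `p` and `r` (one entry per column).
#' @export
edge_f_statistics <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (n < 4L) stop("need at least 4 subjects for screening")
  r <- suppressWarnings(drop(stats::cor(X, y)))
  r[is.na(r)] <- 0  # constant columns
  r2 <- pmin(r^2, 1 - 1e-15)
  f <- r2 * (n - 2) / (1 - r2)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  f[const] <- 0; p[const] <- 1
  list(f = f, p = p, r = r)
}

#' Univariate F-test feature screening
#'
#' Keeps the edges whose univariate regression p-value falls below `alpha`
#' (see [edge_f_statistics()]).
#'
#' @inheritParams edge_f_statistics
#' @param alpha p-value threshold (default 0.05).
#' @return Integer vector of selected column indices (possibly empty).
#' @export
select_features_ftest <- function(X, y, alpha = 0.05) {
  stats <- edge_f_statistics(X, y)
  which(stats$p < alpha)
}

#' Fit a PLS regression with inner-CV component selection
#'
#' Selects the number of latent components by k-fold cross-validation on
#' the training data over the grid 1..`max_components` (capped at the data
#' rank), maximizing the mean Pearson correlation between held-out
#' predictions and observations; ties go to the fewest components. The
#' final model is refit on all training data with the chosen count.
#'
#' @param X numeric matrix of pre-screened training predictors.
#' @param y numeric training response.
#' @param max_components upper bound of the component grid (default 100,
#'   mirroring a 1..100 grid search; clipped with a message suppressed to
#'   min(n - 1, feature count, smallest inner-fold size - 1)).
#' @param inner_folds inner CV folds (default 5).
#' @param seed seed for the inner fold assignment.
#' @return list of class `predictive_model`: `fit` (a `pls1_fit`),
#'   `ncomp`, `cv_r` (mean inner-CV r per grid point), `n_train`,
#'   `n_features`.
#' @export
fit_plsr <- function(X, y, max_components = 100L, inner_folds = 5L,
                     seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= inner_folds) stop("training size must exceed inner_folds")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(inner_folds), n))
  min_train <- n - max(tabulate(fold, inner_folds))
  grid_max <- min(as.integer(max_components), n - 1L, p, min_train - 1L)
  if (grid_max < 1L) grid_max <- 1L
  # one fit per fold at the grid maximum yields every grid point's
  # held-out predictions at once
  cv_pred <- matrix(NA_real_, n, grid_max)
  for (kf in seq_len(inner_folds)) {
    tr <- fold != kf
    if (sum(tr) < 2L || sum(!tr) == 0L) next
    fit <- pls1_fit(X[tr, , drop = FALSE], y[tr], grid_max)
    pr <- pls1_predict(fit, X[!tr, , drop = FALSE], all = TRUE)
    cv_pred[!tr, seq_len(fit$ncomp)] <- pr
    if (fit$ncomp < grid_max)  # rank-limited fold: reuse the last column
      cv_pred[!tr, seq(fit$ncomp + 1L, grid_max)] <- pr[, fit$ncomp]
  }
  cv_r <- vapply(seq_len(grid_max), function(a) {
    ok <- !is.na(cv_pred[, a])
    mean(vapply(seq_len(inner_folds), function(kf) {
      sel <- ok & fold == kf
      if (sum(sel) < 3L) return(NA_real_)
      v <- suppressWarnings(stats::cor(cv_pred[sel, a], y[sel]))
      if (is.na(v)) 0 else v
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  cv_r[is.nan(cv_r)] <- -Inf
  ncomp <- which.max(cv_r)  # which.max takes the first (fewest) on ties
  fit <- pls1_fit(X, y, ncomp)
  structure(list(fit = fit, ncomp = fit$ncomp, cv_r = cv_r,
                 n_train = n, n_features = p),
            class = "predictive_model")
}

#' Predict from a fitted predictive model
#'
#' @param model a `predictive_model` from [fit_plsr()].
#' @param X predictor matrix with the model's feature columns.
#' @return Numeric vector of predictions.
#' @export
predict_plsr <- function(model, X) {
  stopifnot(inherits(model, "predictive_model"))
  pls1_predict(model$fit, X, ncomp = model$ncomp)
}

#' Score a model by predicted-observed Pearson correlation
#'
#' @param model a `predictive_model`.
#' @param X_test test predictor matrix (model's feature columns).
#' @param y_test observed test responses.
#' @return Pearson correlation; 0 (with a warning) when predictions have
#'   zero variance, by documented convention.
#' @export
predict_and_score <- function(model, X_test, y_test) {
  pred <- predict_plsr(model, X_test)
  if (stats::sd(pred) == 0 || stats::sd(y_test) == 0) {
    warning("zero-variance predictions or observations; returning r = 0")
    return(0)
  }
  stats::cor(pred, y_test)
}

# one direction of one LOGOCV iteration: screen on train, fit, score on test
logocv_one_direction <- function(edges, g, train, test, alpha_screen,
                                 max_components, inner_folds) {
  sel <- select_features_ftest(edges[train, , drop = FALSE], g[train],
                               alpha_screen)
  if (length(sel) == 0L) return(list(r = 0, selected = integer(0)))
  model <- fit_plsr(edges[train, sel, drop = FALSE], g[train],
                    max_components, inner_folds)
  r <- suppressWarnings(
    predict_and_score(model, edges[test, sel, drop = FALSE], g[test]))
  list(r = r, selected = sel)
}

#' Cross-twin prediction: twin-split bootstrap with permutation null
#'
#' The leave-one-group-out engine. For each of `B` seeded iterations the
#' pairs are split so each co-twin lands in the opposite group; features
#' are screened on the training group by univariate F test (p <
#' `alpha_screen`), a PLS regression is fitted with inner-CV component
#' selection and scored on the co-twin group by predicted-observed Pearson
#' r. Both fold directions are run (group 1 -> group 2 and the reverse) so
#' edge selections can later be intersected across folds; the reported
#' per-iteration r is the group 1 -> group 2 direction. The null
#' distribution pools, across all B models, `perms_per_model` refits with
#' the training G-scores shuffled (screening rerun on the shuffled
#' response, so the null sees the full pipeline).
#'
#' @param cohort a `twin_cohort` with `g_adjusted` filled.
#' @param zygosity "MZ", "DZ" or NULL.
#' @param B bootstrap iterations (1000 at full scale).
#' @param perms_per_model permutations per model (100 at full scale).
#' @param alpha_screen screening threshold (default 0.05).
#' @param max_components component-grid cap (default 100).
#' @param inner_folds inner CV folds (default 5).
#' @param seed base seed; iteration b uses seed + b for its split and
#'   permutations, giving reproducible, parallelizable streams.
#' @return list of class `prediction_result`: `iteration_r` (length B),
#'   `r_reverse`, `mean_r`, `null_draws` (length B x perms_per_model),
#'   `p_perm`, `selected` (per iteration, list with `train_to_test` and
#'   `test_to_train` edge-index sets), `n_edges`, `params`.
#' @export
run_logocv_bootstrap <- function(cohort, zygosity = NULL, B = 1000L,
                                 perms_per_model = 100L,
                                 alpha_screen = 0.05,
                                 max_components = 100L, inner_folds = 5L,
                                 seed = 1L) {
  sub <- cohort_subset(cohort, zygosity)
  g <- sub$roster$g_adjusted
  if (anyNA(g)) stop("g_adjusted missing; call adjust_cohort_gscore() first")
  if (B < 1L) stop("B must be >= 1")
  edges <- sub$edges
  iteration_r <- r_reverse <- numeric(B)
  null_draws <- if (perms_per_model > 0L)
    matrix(NA_real_, perms_per_model, B) else NULL
  selected <- vector("list", B)
  for (b in seq_len(B)) {
    sp <- split_pairs(sub, NULL, seed = seed + b)
    stopifnot(length(intersect(sp$train_idx, sp$test_idx)) == 0L,
              sort(c(sp$train_idx, sp$test_idx)) == seq_len(nrow(edges)))
    fwd <- logocv_one_direction(edges, g, sp$train_idx, sp$test_idx,
                                alpha_screen, max_components, inner_folds)
    rev <- logocv_one_direction(edges, g, sp$test_idx, sp$train_idx,
                                alpha_screen, max_components, inner_folds)
    iteration_r[b] <- fwd$r
    r_reverse[b] <- rev$r
    selected[[b]] <- list(train_to_test = fwd$selected,
                          test_to_train = rev$selected)
    if (perms_per_model > 0L) {
      set.seed(seed + b)
      for (pp in seq_len(perms_per_model)) {
        g_null <- g
        g_null[sp$train_idx] <- sample(g[sp$train_idx])
        null_draws[pp, b] <- logocv_one_direction(
          edges, g_null, sp$train_idx, sp$test_idx,
          alpha_screen, max_components, inner_folds)$r
      }
    }
  }
  null_vec <- if (is.null(null_draws)) numeric(0) else as.vector(null_draws)
  mean_r <- mean(iteration_r)
  p_perm <- if (length(null_vec)) permutation_pvalue(mean_r, null_vec)
            else NA_real_
  structure(list(iteration_r = iteration_r, r_reverse = r_reverse,
                 mean_r = mean_r, null_draws = null_vec, p_perm = p_perm,
                 selected = selected, n_edges = ncol(edges),
                 params = list(zygosity = zygosity, B = B,
                               perms_per_model = perms_per_model,
                               alpha_screen = alpha_screen,
                               max_components = max_components,
                               inner_folds = inner_folds, seed = seed)),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: mean r = %.3f over %d iteration(s)",
              x$mean_r, length(x$iteration_r)))
  if (!is.na(x$p_perm))
    cat(sprintf(", p_perm = %.4g (%d null draws)", x$p_perm,
                length(x$null_draws)))
  cat("\n")
  invisible(x)
}
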