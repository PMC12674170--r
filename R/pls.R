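#' Partial least squares regression with a single response (PLS1)
#'
#' NIPALS PLS1: predictors are centred and scaled to unit variance, the
#' response is centred, and latent components are extracted sequentially as
#' the directions of maximal covariance with the (deflated) response.
#' Regression coefficients are accumulated per component, so one fit yields
#' predictions for every component count up to `ncomp` — this is what makes
#' the component-grid search cheap.
#'
#' Extraction stops early (with `ncomp` reduced) when the residual
#' covariance vanishes, i.e. when the data support fewer components.
#'
#' @param X numeric matrix, observations x predictors.
#' @param y numeric response vector.
#' @param ncomp maximum number of latent components (capped at
#'   min(nrow - 1, ncol)).
#' @return list of class `pls1_fit`: `coef` (predictors x ncomp matrix of
#'   cumulative coefficients on the standardized scale), `x_mean`, `x_sd`,
#'   `y_mean`, `ncomp`.
#' @export
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (n < 2L || p < 1L) stop("need >= 2 observations and >= 1 predictor")
  ncomp <- min(as.integer(ncomp), n - 1L, p)
  if (ncomp < 1L) stop("ncomp must be >= 1")
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  x_sd[x_sd == 0] <- 1  # constant predictors carry no information
  E <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  y_mean <- mean(y)
  f <- y - y_mean
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w * w))
    if (wn < 1e-12) break
    w <- w / wn
    t <- drop(E %*% w)
    tt <- sum(t * t)
    if (tt < 1e-12) break
    P[, a] <- drop(crossprod(E, t)) / tt
    q[a] <- sum(f * t) / tt
    E <- E - tcrossprod(t, P[, a])
    f <- f - t * q[a]
    W[, a] <- w
    a_used <- a
  }
  if (a_used == 0L) {
    # response orthogonal to all predictors: fall back to the mean model
    return(structure(list(coef = matrix(0, p, 1L), x_mean = x_mean,
                          x_sd = x_sd, y_mean = y_mean, ncomp = 1L),
                     class = "pls1_fit"))
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  R <- W %*% solve(crossprod(P, W))
  # cumulative coefficients: coef[, a] = R[, 1:a] %*% q[1:a]
  coef <- R %*% (q * upper.tri(matrix(1, a_used, a_used), diag = TRUE))
  structure(list(coef = coef, x_mean = x_mean, x_sd = x_sd,
                 y_mean = y_mean, ncomp = a_used),
            class = "pls1_fit")
}

#' Predict from a PLS1 fit
#'
#' @param object a `pls1_fit`.
#' @param X new predictor matrix (same columns as the training matrix).
#' @param ncomp component count to use; defaults to the fitted maximum. If
#'   `ncomp = NULL` with `all = TRUE`, returns an observations x ncomp
#'   matrix of predictions for every component count.
#' @param all return predictions for all component counts at once.
#' @return Numeric vector (or matrix when `all = TRUE`) of predictions.
#' @export
pls1_predict <- function(object, X, ncomp = object$ncomp, all = FALSE) {
  stopifnot(inherits(object, "pls1_fit"))
  X <- as.matrix(X)
  if (ncol(X) != nrow(object$coef)) stop("predictor count mismatch")
  Xs <- sweep(sweep(X, 2L, object$x_mean), 2L, object$x_sd, "/")
  if (all) return(Xs %*% object$coef + object$y_mean)
  if (ncomp < 1L || ncomp > object$ncomp)
    stop("ncomp out of fitted range 1..", object$ncomp)
  drop(Xs %*% object$coef[, ncomp]) + object$y_mean
}
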