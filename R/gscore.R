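#' Adjust G-scores for age and gender
#'
#' Regresses raw general-intelligence scores on age and gender by ordinary
#' least squares and returns the residuals, removing the linear confounding
#' of both demographics. If gender has a single level it is dropped from
#' the design with a warning (same-sex sub-cohorts).
#'
#' @param g_raw numeric vector of raw G-scores.
#' @param age numeric vector of ages (years).
#' @param gender binary indicator vector (0/1).
#' @return Numeric vector of residuals (mean zero).
#' @export
adjust_gscore <- function(g_raw, age, gender) {
  n <- length(g_raw)
  if (length(age) != n || length(gender) != n)
    stop("g_raw, age and gender must have equal length")
  if (n < 3L) stop("need at least 3 subjects to adjust")
  if (anyNA(g_raw) || anyNA(age) || anyNA(gender))
    stop("missing values in adjustment inputs")
  if (length(unique(gender)) < 2L) {
    warning("gender has a single level; dropped from the adjustment design")
    X <- cbind(1, age)
  } else {
    X <- cbind(1, age, gender)
  }
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient adjustment design (collinear age/gender)")
  fit <- stats::lm.fit(X, g_raw)
  res <- fit$residuals
  stopifnot(abs(mean(res)) < 1e-10)
  unname(res)
}

#' Adjust a cohort's G-scores in place
#'
#' Fills the `g_adjusted` roster column from [adjust_gscore()], using all
#' subjects jointly.
#'
#' @param cohort a `twin_cohort`.
#' @return The cohort with `g_adjusted` populated.
#' @export
adjust_cohort_gscore <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  ro <- cohort$roster
  cohort$roster$g_adjusted <- adjust_gscore(ro$g_raw, ro$age, ro$gender)
  cohort
}

#' Twin-pair correlation of adjusted G-scores
#'
#' Pearson correlation across pairs between the two co-twins' adjusted
#' G-scores. Because no natural ordering of twins within a pair exists,
#' two conventions are offered: `"roster"` pairs member 1 with member 2 in
#' roster order; `"double_entry"` correlates the doubled pairing
#' \{(a,b), (b,a)\}, which is invariant to member order (its p-value is not
#' reported, as the doubled observations are not independent).
#'
#' @param cohort a `twin_cohort` with `g_adjusted` filled.
#' @param zygosity "MZ" or "DZ".
#' @param method "roster" (default) or "double_entry".
#' @return list with `r`, `p` (NA for double entry) and `n_pairs`.
#' @export
twin_pair_correlation <- function(cohort, zygosity,
                                  method = c("roster", "double_entry")) {
  method <- match.arg(method)
  sub <- cohort_subset(cohort, zygosity)
  g <- sub$roster$g_adjusted
  if (anyNA(g)) stop("g_adjusted missing; call adjust_cohort_gscore() first")
  pi <- pair_index(sub)
  if (nrow(pi) < 3L) stop("need at least 3 ", zygosity, " pairs")
  a <- g[pi$m1]; b <- g[pi$m2]
  if (method == "roster") {
    ct <- stats::cor.test(a, b)
    list(r = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(pi))
  } else {
    r <- stats::cor(c(a, b), c(b, a))
    list(r = r, p = NA_real_, n_pairs = nrow(pi))
  }
}

#' Falconer heritability estimate
#'
#' Classical additive-heritability estimator from twin correlations,
#' h2 = 2 (rMZ - rDZ). Values outside [0, 1] are reported as computed,
#' with a warning, since the estimator is unbounded.
#'
#' @param r_mz,r_dz Pearson correlations of MZ and DZ co-twin scores.
#' @return list of class `heritability_estimate` with `r_mz`, `r_dz`, `h2`.
#' @export
#' @examples
#' falconer_h2(0.78, 0.42)$h2  # 0.72
falconer_h2 <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1)
    stop("correlations must lie in [-1, 1]")
  h2 <- 2 * (r_mz - r_dz)
  if (h2 < 0 || h2 > 1)
    warning("Falconer h2 = ", signif(h2, 4), " lies outside [0, 1]")
  structure(list(r_mz = r_mz, r_dz = r_dz, h2 = h2),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("Falconer h2 = %.3f  (rMZ = %.3f, rDZ = %.3f)\n",
              x$h2, x$r_mz, x$r_dz))
  invisible(x)
}
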