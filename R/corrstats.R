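#' Fisher z transform of a correlation
#'
#' z = atanh(r). Inputs with |r| >= 1 are clamped to +/-(1 - 1e-12) with a
#' warning so the transform stays finite.
#'
#' @param r Pearson correlation(s).
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(abs(r) >= 1)) {
    warning("|r| = 1 clamped to 1 - 1e-12 before Fisher transform")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  atanh(r)
}

check_corr_inputs <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  if (abs(r1) > 1 || abs(r2) > 1) stop("correlations must lie in [-1, 1]")
}

#' Compare two independent correlations (Fisher z test, Cohen's q)
#'
#' Tests the difference between correlations observed in two independent
#' groups: z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with a
#' two-tailed standard-normal p-value. Cohen's q = atanh(r1) - atanh(r2)
#' is the effect size on the Fisher-z scale.
#'
#' Note on sample sizes: when the correlations being compared were computed
#' over individuals, n is the individual count; when computed over twin
#' pairs (one observation per pair), n is the pair count. The caller states
#' the convention explicitly by passing the matching n.
#'
#' @param r1,r2 the two correlations.
#' @param n1,n2 the corresponding sample sizes (> 3).
#' @return list with `z_stat`, `p_two_tailed`, `q`.
#' @export
#' @examples
#' compare_independent_correlations(0.35, 178, 0.07, 100)$z_stat  # ~2.33
compare_independent_correlations <- function(r1, n1, r2, n2) {
  check_corr_inputs(r1, n1, r2, n2)
  q <- atanh(r1) - atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- q / se
  list(z_stat = z, p_two_tailed = 2 * stats::pnorm(-abs(z)), q = q)
}

#' Zou's confidence interval for a difference of independent correlations
#'
#' Builds the asymmetric CI for r1 - r2 from the individual correlations'
#' Fisher-z confidence limits back-transformed by tanh (Zou, 2007):
#' with per-correlation limits (l_k, u_k),
#' L = r1 - r2 - sqrt((r1-l1)^2 + (u2-r2)^2) and
#' U = r1 - r2 + sqrt((u1-r1)^2 + (r2-l2)^2).
#'
#' @inheritParams compare_independent_correlations
#' @param conf confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
#' @examples
#' round(zou_ci(0.35, 178, 0.07, 100), 3)  # 0.044 0.513
zou_ci <- function(r1, n1, r2, n2, conf = 0.95) {
  check_corr_inputs(r1, n1, r2, n2)
  if (conf <= 0 || conf >= 1) stop("conf must lie in (0, 1)")
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  l1 <- tanh(atanh(r1) - zc / sqrt(n1 - 3))
  u1 <- tanh(atanh(r1) + zc / sqrt(n1 - 3))
  l2 <- tanh(atanh(r2) - zc / sqrt(n2 - 3))
  u2 <- tanh(atanh(r2) + zc / sqrt(n2 - 3))
  d <- r1 - r2
  c(ci_low = d - sqrt((r1 - l1)^2 + (u2 - r2)^2),
    ci_high = d + sqrt((u1 - r1)^2 + (r2 - l2)^2))
}

#' Power to detect a difference between two independent correlations
#'
#' Normal approximation for the two-tailed Fisher-z test at effect size q
#' (the difference of Fisher-z-transformed correlations):
#' with z_eff = q / sqrt(1/(n1-3) + 1/(n2-3)),
#' power = Phi(z_eff - z_{alpha/2}) + Phi(-z_eff - z_{alpha/2}).
#' At q = 0 this returns alpha (the test size), as it should.
#'
#' @param q Cohen's q effect size.
#' @param n1,n2 group sample sizes (> 3).
#' @param alpha two-tailed significance level, default 0.05.
#' @return Power in [0, 1].
#' @export
#' @examples
#' power_two_correlations(0.3760, 89, 50)  # ~0.545
power_two_correlations <- function(q, n1, n2, alpha = 0.05) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  zc <- stats::qnorm(1 - alpha / 2)
  ze <- q / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  stats::pnorm(ze - zc) + stats::pnorm(-ze - zc)
}

#' Full comparison of two independent correlations
#'
#' Convenience wrapper bundling the Fisher z test, Cohen's q, Zou's CI and
#' the power approximation into one `corr_comparison` object.
#'
#' @inheritParams compare_independent_correlations
#' @param conf confidence level for Zou's CI.
#' @param alpha significance level for the power approximation.
#' @return list of class `corr_comparison`.
#' @export
correlation_comparison <- function(r1, n1, r2, n2, conf = 0.95,
                                   alpha = 0.05) {
  cmp <- compare_independent_correlations(r1, n1, r2, n2)
  ci <- zou_ci(r1, n1, r2, n2, conf)
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
                 z_stat = cmp$z_stat, p_two_tailed = cmp$p_two_tailed,
                 q = cmp$q, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 conf = conf,
                 power = power_two_correlations(cmp$q, n1, n2, alpha)),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf("r1 = %.3f (n = %d) vs r2 = %.3f (n = %d)\n",
              x$r1, x$n1, x$r2, x$n2))
  cat(sprintf("Fisher z = %.2f, p = %.4g (two-tailed), q = %.4f\n",
              x$z_stat, x$p_two_tailed, x$q))
  cat(sprintf("Zou %d%% CI for r1 - r2: [%.3f, %.3f]; power = %.3f\n",
              round(100 * x$conf), x$ci_low, x$ci_high, x$power))
  invisible(x)
}

#' One-sided permutation p-value
#'
#' Add-one permutation p-value for a larger-is-better statistic:
#' p = (1 + #\{null >= observed\}) / (1 + N). Never returns exactly 0, in
#' keeping with the finite number of permutations.
#'
#' @param observed observed statistic.
#' @param null_draws numeric vector of statistics under the null (N >= 1).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null_draws) {
  if (length(null_draws) == 0L) stop("empty null distribution")
  if (anyNA(null_draws) || is.na(observed))
    stop("missing values in permutation statistics")
  (1 + sum(null_draws >= observed)) / (1 + length(null_draws))
}
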