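#' Parameters for the synthetic twin-cohort generator
#'
#' The generator draws, for each pair p, a latent edge profile g_p with
#' independent standard-normal entries and gives member i the edge vector
#' x_i = sqrt(rho) g_p + sqrt(1 - rho) e_i (e_i independent standard
#' normal), so every edge has unit variance and within-pair correlation
#' rho. The G-score is G_i = beta * sum_j w_j x_ij over a sparse set of
#' causal edges (fixed equal-magnitude, unit-norm weights w), plus a
#' shared-pair environmental term s_p ~ N(0, shared_env) and individual
#' noise sigma * eps_i. Ages are drawn uniformly on 22-36 years (shared
#' within pair) and genders Bernoulli(0.5) per pair (same-sex pairs).
#'
#' Presets: `zygosity = "MZ"` defaults rho to 0.8 and `"DZ"` to 0.2,
#' mirroring the qualitative monozygotic/dizygotic contrast in within-pair
#' connectome similarity.
#'
#' @param n_pairs number of twin pairs (default 89).
#' @param n_nodes parcellation size R (default 268; use 40 for desk-scale
#'   work).
#' @param rho within-pair edge correlation in [0, 1]; defaults to the
#'   zygosity preset.
#' @param causal_edge_count number of causal edges k (default 79).
#' @param beta edge-to-G coupling (default 1).
#' @param sigma individual G noise SD (default 1).
#' @param shared_env variance of the shared-pair G component (default 0).
#' @param zygosity "MZ" or "DZ" label stamped on the cohort (default "MZ").
#' @param causal_network optional network label: causal edges are drawn
#'   from that network's intra-network edges instead of uniformly.
#' @param atlas atlas used to resolve `causal_network`; defaults to
#'   [scaled_atlas()] of `n_nodes`.
#' @param age_beta,gender_beta optional linear demographic effects added to
#'   the raw G-score (default 0); the age/gender adjustment removes them.
#' @param seed integer RNG seed.
#' @return list of class `twin_sim_params`.
#' @export
twin_sim_params <- function(n_pairs = 89L, n_nodes = 268L, rho = NULL,
                            causal_edge_count = 79L, beta = 1,
                            sigma = 1, shared_env = 0,
                            zygosity = c("MZ", "DZ"),
                            causal_network = NULL, atlas = NULL,
                            age_beta = 0, gender_beta = 0, seed = 1L) {
  zygosity <- match.arg(zygosity)
  if (is.null(rho)) rho <- if (zygosity == "MZ") 0.8 else 0.2
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (sigma < 0) stop("sigma must be >= 0")
  if (shared_env < 0) stop("shared_env must be >= 0")
  if (n_pairs < 2L) stop("need at least 2 pairs")
  if (n_nodes < 3L) stop("need at least 3 nodes")
  if (causal_edge_count < 1L || causal_edge_count > n_edges(n_nodes))
    stop("causal_edge_count must lie in 1..", n_edges(n_nodes))
  if (!is.null(causal_network) && is.null(atlas))
    atlas <- scaled_atlas(n_nodes)
  structure(list(n_pairs = as.integer(n_pairs),
                 n_nodes = as.integer(n_nodes), rho = rho,
                 causal_edge_count = as.integer(causal_edge_count),
                 beta = beta, sigma = sigma, shared_env = shared_env,
                 zygosity = zygosity, causal_network = causal_network,
                 atlas = atlas, age_beta = age_beta,
                 gender_beta = gender_beta, seed = as.integer(seed)),
            class = "twin_sim_params")
}

#' Generate a synthetic twin cohort
#'
#' Draws a cohort under the model described in [twin_sim_params()] and
#' returns it with its ground truth attached (causal edge indices, causal
#' weights, per-pair shared components and the parameters), so
#' parameter-recovery and calibration tests can check the pipeline against
#' known structure. Identical parameters and seed give a byte-identical
#' cohort.
#'
#' @param params a `twin_sim_params`.
#' @return A `twin_cohort` (class also `synthetic_cohort`) whose `truth`
#'   field holds `causal_edges`, `weights`, `shared_component`, `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "twin_sim_params"))
  set.seed(params$seed)
  np <- params$n_pairs
  m <- n_edges(params$n_nodes)
  k <- params$causal_edge_count
  if (!is.null(params$causal_network)) {
    candidates <- intra_network_edge_indices(params$atlas,
                                             params$causal_network)
    if (length(candidates) < k)
      stop("network '", params$causal_network, "' has only ",
           length(candidates), " intra-network edges; reduce ",
           "causal_edge_count")
    causal <- sort(sample(candidates, k))
  } else {
    causal <- sort(sample.int(m, k))
  }
  w <- rep(1 / sqrt(k), k)  # equal magnitude, unit norm
  latent <- matrix(stats::rnorm(np * m), np, m)
  x1 <- sqrt(params$rho) * latent +
    sqrt(1 - params$rho) * matrix(stats::rnorm(np * m), np, m)
  x2 <- sqrt(params$rho) * latent +
    sqrt(1 - params$rho) * matrix(stats::rnorm(np * m), np, m)
  s_p <- stats::rnorm(np, 0, sqrt(params$shared_env))
  signal1 <- params$beta * drop(x1[, causal, drop = FALSE] %*% w)
  signal2 <- params$beta * drop(x2[, causal, drop = FALSE] %*% w)
  g1 <- signal1 + s_p + params$sigma * stats::rnorm(np)
  g2 <- signal2 + s_p + params$sigma * stats::rnorm(np)
  age <- sample(22:36, np, replace = TRUE)
  gender <- stats::rbinom(np, 1L, 0.5)
  demo <- params$age_beta * age + params$gender_beta * gender
  pair_ids <- sprintf("%s_pair%03d", params$zygosity, seq_len(np))
  roster <- data.frame(
    subject_id = as.vector(rbind(paste0(pair_ids, "_a"),
                                 paste0(pair_ids, "_b"))),
    pair_id = rep(pair_ids, each = 2L),
    zygosity = params$zygosity,
    age = rep(age, each = 2L),
    gender = rep(gender, each = 2L),
    g_raw = as.vector(rbind(g1 + demo, g2 + demo)),
    stringsAsFactors = FALSE)
  edges <- matrix(NA_real_, 2L * np, m)
  edges[seq(1L, 2L * np, by = 2L), ] <- x1
  edges[seq(2L, 2L * np, by = 2L), ] <- x2
  cohort <- twin_cohort(roster, edges, params$n_nodes)
  cohort$truth <- list(causal_edges = causal, weights = w,
                       shared_component = s_p, params = params)
  class(cohort) <- c("synthetic_cohort", class(cohort))
  cohort
}

#' Model-implied co-twin G-score correlation
#'
#' Under the generator's model (unit-norm causal weights, unit-variance
#' edges), the expected Pearson correlation between co-twin G-scores is
#' r = (beta^2 rho + c) / (beta^2 + sigma^2 + c), with c the shared
#' environmental variance. Used as the analytic oracle in
#' parameter-recovery tests.
#'
#' @param params a `twin_sim_params`.
#' @return Expected Pearson correlation.
#' @export
analytic_twin_g_correlation <- function(params) {
  stopifnot(inherits(params, "twin_sim_params"))
  tot <- params$beta^2 + params$sigma^2 + params$shared_env
  if (tot <= 0) stop("total G variance is zero")
  (params$beta^2 * params$rho + params$shared_env) / tot
}

#' Emit a synthetic BOLD run consistent with an edge vector
#'
#' Generates a timepoints x nodes Gaussian series whose population
#' correlation matrix is tanh of the (devectorized) Fisher-z edge vector,
#' clipped to the nearest positive-definite matrix by eigenvalue flooring.
#' The empirical FC of the emitted series therefore approximates the edge
#' vector (up to sampling noise and the PD projection); this exists to
#' exercise the time-series ingestion path, not to model haemodynamics.
#'
#' @param edge_vector Fisher-z edge vector (package ordering).
#' @param n_timepoints samples to draw (default 200).
#' @param seed RNG seed.
#' @return Numeric matrix, n_timepoints x nodes.
#' @export
simulate_run_timeseries <- function(edge_vector, n_timepoints = 200L,
                                    seed = 1L) {
  sigma <- tanh(devectorize_edges(edge_vector))
  diag(sigma) <- 1
  eg <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-6)
  root <- eg$vectors %*% (sqrt(vals) * t(eg$vectors))
  set.seed(seed)
  r <- nrow(sigma)
  matrix(stats::rnorm(n_timepoints * r), n_timepoints, r) %*% root
}
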