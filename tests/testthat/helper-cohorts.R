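# fixtures built in code: small cohorts and matrices shared across tests

make_cohort <- function(n_pairs = 20, n_nodes = 12, rho = 0.8,
                        causal = 6, beta = 1, sigma = 1, shared_env = 0,
                        zygosity = "MZ", seed = 1, ...) {
  adjust_cohort_gscore(generate_cohort(twin_sim_params(
    n_pairs = n_pairs, n_nodes = n_nodes, rho = rho,
    causal_edge_count = causal, beta = beta, sigma = sigma,
    shared_env = shared_env, zygosity = zygosity, seed = seed, ...)))
}

# hand-built 3-pair cohort with fully controlled edge vectors and G-scores
tiny_cohort <- function(edge_rows, g, zygosity = "MZ") {
  n <- nrow(edge_rows)
  stopifnot(n %% 2 == 0)
  rownames(edge_rows) <- NULL
  roster <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    pair_id = rep(sprintf("p%02d", seq_len(n / 2)), each = 2),
    zygosity = zygosity,
    age = rep(c(25, 30), length.out = n),
    gender = rep(c(0, 1), each = 2, length.out = n),
    g_raw = g)
  co <- twin_cohort(roster, edge_rows)
  co$roster$g_adjusted <- g  # bypass adjustment: tests control G directly
  co
}

sym_matrix <- function(r, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(r * r), r, r)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
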