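test_that("degenerate limits behave: rho = 1 duplicates, rho = 0 decouples", {
  co1 <- generate_cohort(twin_sim_params(n_pairs = 10, n_nodes = 8,
                                         rho = 1, sigma = 0,
                                         causal_edge_count = 5, seed = 2))
  a <- seq(1, 20, 2); b <- seq(2, 20, 2)
  expect_equal(co1$edges[a, ], co1$edges[b, ], ignore_attr = TRUE)
  expect_equal(co1$roster$g_raw[a], co1$roster$g_raw[b])
  co0 <- generate_cohort(twin_sim_params(n_pairs = 400, n_nodes = 8,
                                         rho = 0, causal_edge_count = 5,
                                         seed = 3))
  a <- seq(1, 800, 2); b <- seq(2, 800, 2)
  within_r <- mean(vapply(seq_len(ncol(co0$edges)), function(j)
    cor(co0$edges[a, j], co0$edges[b, j]), numeric(1)))
  expect_lt(abs(within_r), 0.02)
})

test_that("within-pair edge correlation matches rho (moment oracle)", {
  co <- generate_cohort(twin_sim_params(n_pairs = 500, n_nodes = 10,
                                        rho = 0.6, causal_edge_count = 5,
                                        seed = 5))
  a <- seq(1, 1000, 2); b <- seq(2, 1000, 2)
  within_r <- mean(vapply(seq_len(ncol(co$edges)), function(j)
    cor(co$edges[a, j], co$edges[b, j]), numeric(1)))
  expect_lt(abs(within_r - 0.6), 0.02)
})

test_that("G variance and twin correlation match the analytic model", {
  p <- twin_sim_params(n_pairs = 2000, n_nodes = 10, rho = 0.7,
                       causal_edge_count = 6, beta = 1.2, sigma = 0.8,
                       shared_env = 0.4, seed = 6)
  expect_equal(analytic_twin_g_correlation(p),
               (1.2^2 * 0.7 + 0.4) / (1.2^2 + 0.8^2 + 0.4))
  expect_equal(analytic_twin_g_correlation(
    twin_sim_params(rho = 0.8, beta = 1, sigma = 0, shared_env = 0)), 0.8)
  expect_equal(analytic_twin_g_correlation(
    twin_sim_params(rho = 0.8, beta = 0, sigma = 1, shared_env = 0)), 0)
  co <- adjust_cohort_gscore(generate_cohort(p))
  expect_lt(abs(var(co$roster$g_raw) - (1.2^2 + 0.8^2 + 0.4)), 0.15)
  r_emp <- twin_pair_correlation(co, "MZ")$r
  expect_lt(abs(r_emp - analytic_twin_g_correlation(p)), 0.05)
})

test_that("Falconer h2 on generated MZ/DZ cohorts recovers the model value", {
  base <- list(n_pairs = 1500, n_nodes = 10, causal_edge_count = 6,
               beta = 1, sigma = 1, shared_env = 0)
  mz <- adjust_cohort_gscore(generate_cohort(do.call(twin_sim_params,
    c(base, list(rho = 0.8, zygosity = "MZ", seed = 7)))))
  dz <- adjust_cohort_gscore(generate_cohort(do.call(twin_sim_params,
    c(base, list(rho = 0.2, zygosity = "DZ", seed = 8)))))
  h <- falconer_h2(twin_pair_correlation(mz, "MZ")$r,
                   twin_pair_correlation(dz, "DZ")$r)
  expected <- 2 * 1 * (0.8 - 0.2) / (1 + 1)  # 2 beta^2 (rho_mz - rho_dz) / var
  expect_lt(abs(h$h2 - expected), 0.08)
})

test_that("generation is byte-identical under a fixed seed", {
  p <- twin_sim_params(n_pairs = 8, n_nodes = 8, rho = 0.5,
                       causal_edge_count = 4, seed = 9)
  expect_identical(generate_cohort(p), generate_cohort(p))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(twin_sim_params(rho = 1.2), "rho")
  expect_error(twin_sim_params(sigma = -1), "sigma")
  expect_error(twin_sim_params(n_nodes = 8, causal_edge_count = 100),
               "causal_edge_count")
  expect_error(twin_sim_params(n_pairs = 1), "2 pairs")
  expect_error(generate_cohort(twin_sim_params(
    n_nodes = 20, causal_edge_count = 50, causal_network = "DMN")),
    "intra-network edges")
})

test_that("network-planted causal edges stay inside the named network", {
  atlas <- scaled_atlas(20)
  co <- generate_cohort(twin_sim_params(n_pairs = 5, n_nodes = 20,
                                        causal_edge_count = 3,
                                        causal_network = "MOT",
                                        atlas = atlas, seed = 10))
  expect_true(all(co$truth$causal_edges %in%
                    intra_network_edge_indices(atlas, "MOT")))
})

test_that("demographic effects are injected and removed by adjustment", {
  p <- twin_sim_params(n_pairs = 300, n_nodes = 8, rho = 0.5,
                       causal_edge_count = 4, age_beta = 0.3,
                       gender_beta = 2, seed = 11)
  co <- generate_cohort(p)
  expect_gt(cor(co$roster$g_raw, co$roster$age), 0.4)
  co <- adjust_cohort_gscore(co)
  expect_lt(abs(cor(co$roster$g_adjusted, co$roster$age)), 1e-10)
})

test_that("emitted time series reproduce their target FC approximately", {
  set.seed(12)
  target <- vectorize_lower_triangle(sym_matrix(6) * 0.3)
  ts <- simulate_run_timeseries(target, n_timepoints = 4000, seed = 13)
  expect_identical(dim(ts), c(4000L, 6L))
  emp <- vectorize_lower_triangle(compute_fc_matrix(ts))
  expect_lt(max(abs(emp - target)), 0.12)
})

test_that("cohorts round-trip through delimited files", {
  co <- make_cohort(n_pairs = 5, n_nodes = 8, seed = 14)
  stem <- file.path(withr::local_tempdir(), "cohort")
  write_cohort(co, stem)
  back <- read_cohort(stem)
  expect_equal(back$roster$g_raw, co$roster$g_raw, tolerance = 1e-12)
  expect_equal(unname(back$edges), unname(co$edges), tolerance = 1e-10)
  expect_identical(back$roster$pair_id, co$roster$pair_id)
})
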