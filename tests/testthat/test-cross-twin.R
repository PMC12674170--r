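test_that("twin splits are disjoint, pair-respecting and seed-determined", {
  co <- make_cohort(n_pairs = 3, n_nodes = 6, seed = 2)
  sp <- split_pairs(co, "MZ", seed = 10)
  expect_length(sp$train_idx, 3)
  expect_length(sp$test_idx, 3)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  pid <- co$roster$pair_id
  expect_identical(sort(pid[sp$train_idx]), sort(unique(pid)))
  sp2 <- split_pairs(co, "MZ", seed = 10)
  expect_identical(sp, sp2)
  expect_false(identical(sp$train_idx,
                         split_pairs(co, "MZ", seed = 11)$train_idx))
})

test_that("each member lands in training about half the time (binomial)", {
  co <- make_cohort(n_pairs = 4, n_nodes = 6, seed = 3)
  n_draws <- 400
  first_in_train <- vapply(seq_len(n_draws), function(s)
    1L %in% split_pairs(co, "MZ", seed = s)$train_idx, logical(1))
  # binomial oracle: 3 sigma band around 0.5
  expect_lt(abs(mean(first_in_train) - 0.5), 3 * sqrt(0.25 / n_draws))
})

test_that("screening F statistics equal per-edge simple-regression F", {
  set.seed(17)
  X <- matrix(rnorm(8 * 20), 8, 20)
  y <- rnorm(8)
  st <- edge_f_statistics(X, y)
  for (j in 1:20) {
    an <- anova(lm(y ~ X[, j]))  # explicit OLS oracle
    expect_equal(st$f[j], an$`F value`[1], tolerance = 1e-8)
    expect_equal(st$p[j], an$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("screening selects signal, skips constants, calibrates at alpha", {
  set.seed(19)
  X <- matrix(rnorm(30 * 50), 30, 50)
  y <- X[, 7]  # one edge equal to the response
  sel <- select_features_ftest(X, y, alpha = 0.05)
  expect_true(7 %in% sel)
  expect_lt(edge_f_statistics(X, y)$p[7], 1e-12)
  Xc <- X; Xc[, 3] <- 2
  expect_false(3 %in% select_features_ftest(Xc, y))
  # type-I calibration: null response selects ~ alpha * m edges
  m <- 400; reps <- 30
  rate <- mean(replicate(reps, {
    Xn <- matrix(rnorm(20 * m), 20, m)
    length(select_features_ftest(Xn, rnorm(20), alpha = 0.05)) / m
  }))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / (reps * m)) + 0.005)
})

test_that("prediction scoring is the Pearson correlation with conventions", {
  y <- c(0.3, -1, 2, 0.7, -0.2)
  model <- structure(list(fit = pls1_fit(matrix(y), y, 1), ncomp = 1,
                          n_train = 5, n_features = 1),
                     class = "predictive_model")
  expect_equal(predict_and_score(model, matrix(y), y), 1, tolerance = 1e-10)
  expect_equal(predict_and_score(model, matrix(-y + 0.4), y), -1,
               tolerance = 1e-10)
  # arithmetic oracle on a hand-built prediction set
  pred <- c(1, 2, 3, 4, 5); obs <- c(2, 1, 4, 3, 6)
  oracle <- sum((pred - 3) * (obs - mean(obs))) /
    sqrt(sum((pred - 3)^2) * sum((obs - mean(obs))^2))
  expect_equal(cor(pred, obs), oracle, tolerance = 1e-12)
  expect_warning(
    r0 <- predict_and_score(model, matrix(rep(0.5, 5)), y),
    "zero-variance")
  expect_equal(r0, 0)
})

test_that("the bootstrap engine is reproducible and leakage-free", {
  co <- make_cohort(n_pairs = 12, n_nodes = 10, seed = 5)
  res1 <- run_logocv_bootstrap(co, "MZ", B = 1, perms_per_model = 3,
                               max_components = 5, seed = 42)
  res2 <- run_logocv_bootstrap(co, "MZ", B = 1, perms_per_model = 3,
                               max_components = 5, seed = 42)
  expect_identical(res1, res2)
  expect_length(res1$iteration_r, 1)
  expect_length(res1$null_draws, 3)
  expect_equal(res1$mean_r, mean(res1$iteration_r))
  expect_equal(res1$p_perm,
               permutation_pvalue(res1$mean_r, res1$null_draws))
})

test_that("with rho = 1 and no G noise the co-twin group mirrors training", {
  co <- make_cohort(n_pairs = 10, n_nodes = 8, rho = 1, sigma = 0,
                    causal = 5, seed = 8)
  # co-twin data identical: scoring on the test group equals scoring on train
  res <- run_logocv_bootstrap(co, "MZ", B = 2, perms_per_model = 0,
                              max_components = 4, seed = 9)
  for (b in 1:2) {
    sp <- split_pairs(co, "MZ", seed = 9 + b)
    g <- co$roster$g_adjusted
    sel <- select_features_ftest(co$edges[sp$train_idx, ], g[sp$train_idx])
    model <- fit_plsr(co$edges[sp$train_idx, sel, drop = FALSE],
                      g[sp$train_idx], max_components = 4, inner_folds = 5)
    r_train <- predict_and_score(model,
                                 co$edges[sp$train_idx, sel, drop = FALSE],
                                 g[sp$train_idx])
    expect_equal(res$iteration_r[b], r_train, tolerance = 1e-10)
  }
})

test_that("MZ-like cohorts out-predict DZ-like ones; nulls centre at zero", {
  mz <- make_cohort(n_pairs = 30, n_nodes = 12, rho = 0.9, causal = 8,
                    sigma = 0.5, seed = 30)
  dz <- make_cohort(n_pairs = 30, n_nodes = 12, rho = 0.1, causal = 8,
                    sigma = 0.5, zygosity = "DZ", seed = 30)
  rm_ <- run_logocv_bootstrap(mz, "MZ", B = 15, perms_per_model = 4,
                              max_components = 8, seed = 7)
  rd <- run_logocv_bootstrap(dz, "DZ", B = 15, perms_per_model = 4,
                             max_components = 8, seed = 7)
  expect_gt(rm_$mean_r, rd$mean_r)
  nd <- rm_$null_draws
  expect_lt(abs(mean(nd)), 3 * sd(nd) / sqrt(length(nd)) + 0.05)
})
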