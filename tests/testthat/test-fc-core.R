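test_that("compute_fc_matrix matches hand-computed Pearson r on a toy", {
  # 4 timepoints x 3 nodes; oracle: explicit covariance-sum formula
  ts <- matrix(c(1, 2, 4, 3,
                 2, 1, 5, 6,
                 9, 4, 2, 1), nrow = 4)
  oracle_r <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  z <- compute_fc_matrix(ts)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) expect_identical(z[i, j], 0)
    else expect_equal(z[i, j], atanh(oracle_r(ts[, i], ts[, j])),
                      tolerance = 1e-12)
  }
  expect_equal(z, t(z))
})

test_that("perfect correlation and anti-correlation are clamped to large z", {
  ts <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(5, 1, 7, 2))
  expect_warning(z <- compute_fc_matrix(ts), "clamped")
  expect_gt(z[1, 2], 10)  # atanh(1 - 1e-12) ~ 14
  ts2 <- cbind(c(1, 2, 3, 4), -c(1, 2, 3, 4), c(5, 1, 7, 2))
  expect_warning(z2 <- compute_fc_matrix(ts2), "clamped")
  expect_lt(z2[1, 2], -10)
})

test_that("compute_fc_matrix rejects bad input and names offending nodes", {
  expect_error(compute_fc_matrix(matrix(1:4, 1)), "2 timepoints")
  expect_error(compute_fc_matrix(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance.*a")
  m <- matrix(rnorm(20), 5); m[2, 2] <- NA
  expect_error(compute_fc_matrix(m), "missing")
})

test_that("FC is invariant to affine rescaling of any column", {
  set.seed(7)
  ts <- matrix(rnorm(60), 12, 5)
  z1 <- compute_fc_matrix(ts)
  ts2 <- ts
  ts2[, 3] <- 5 * ts[, 3] - 2
  ts2[, 1] <- -0.1 * ts[, 1] + 100
  z2 <- compute_fc_matrix(ts2)
  z2[, 1] <- -z2[, 1]; z2[1, ] <- -z2[1, ]  # sign flip from negative scale
  diag(z2) <- 0
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("average_runs is the element-wise mean with shape checks", {
  m <- sym_matrix(4)
  expect_silent(expect_equal(average_runs(list(m, m, m, m)), m))
  expect_warning(z <- average_runs(list(m, -m)), "2 run")
  expect_equal(z, matrix(0, 4, 4))
  a <- sym_matrix(3, seed = 2); b <- sym_matrix(3, seed = 3)
  expect_warning(avg <- average_runs(list(a, b)))
  for (i in 1:3) for (j in 1:3)
    expect_equal(avg[i, j], (a[i, j] + b[i, j]) / 2)
  expect_error(average_runs(list(a, sym_matrix(4))), "same node count")
  expect_error(average_runs(list()), "non-empty")
})

test_that("vectorization follows the documented row-major i>j order", {
  m <- matrix(0, 3, 3)
  m[2, 1] <- m[1, 2] <- 0.5
  m[3, 1] <- m[1, 3] <- -0.2
  m[3, 2] <- m[2, 3] <- 0.9
  expect_equal(vectorize_lower_triangle(m), c(0.5, -0.2, 0.9))
  expect_length(vectorize_lower_triangle(sym_matrix(10)), 45)
  expect_identical(n_edges(268), 35778L)
  asym <- sym_matrix(4); asym[1, 2] <- asym[1, 2] + 1e-3
  expect_error(vectorize_lower_triangle(asym), "asymmetric")
})

test_that("vectorize and devectorize are mutually inverse", {
  m <- sym_matrix(8, seed = 5)
  v <- vectorize_lower_triangle(m)
  expect_equal(devectorize_edges(v), m)
  set.seed(9)
  v2 <- rnorm(n_edges(7))
  expect_equal(vectorize_lower_triangle(devectorize_edges(v2)), v2)
  expect_error(devectorize_edges(rnorm(7)), "not R\\(R-1\\)/2")
})

test_that("edge index <-> node pair mapping is the enumeration bijection", {
  expect_equal(edge_to_nodes(1, 3), cbind(i = 2L, j = 1L))
  # enumeration oracle: list all pairs (i > j) in row-major order
  enum <- do.call(rbind, lapply(2:10, function(i)
    cbind(i = i, j = seq_len(i - 1))))
  expect_equal(unname(edge_to_nodes(45, 10)), unname(enum[45, , drop = FALSE]))
  for (k in seq_len(n_edges(10)))
    expect_equal(unname(edge_to_nodes(k, 10)[1, ]), unname(enum[k, ]))
  # round trip over all edges of an 8-node graph
  for (k in seq_len(n_edges(8))) {
    ij <- edge_to_nodes(k, 8)
    expect_identical(nodes_to_edge(ij[1, "i"], ij[1, "j"], 8), k)
    expect_identical(nodes_to_edge(ij[1, "j"], ij[1, "i"], 8), k)
  }
  expect_error(edge_to_nodes(0, 5), "out of range")
  expect_error(edge_to_nodes(11, 5), "out of range")
  expect_error(nodes_to_edge(2, 2, 5), "self-edges")
})

test_that("intra-network edge sets have size m(m-1)/2 and partition cleanly", {
  atlas <- canonical_atlas()
  expect_identical(sum(canonical_network_sizes()), 268L)
  expect_length(intra_network_edge_indices(atlas, "DMN"), 153)   # 18*17/2
  expect_length(intra_network_edge_indices(atlas, "VISII"), 36)  # 9*8/2
  expect_error(intra_network_edge_indices(atlas, "nope"),
               "valid networks.*MFN")
  one <- network_atlas(c("A", "B", "B", "B"))
  expect_length(intra_network_edge_indices(one, "A"), 0)
  # conservation: intra counts + inter count = total edges
  small <- scaled_atlas(30)
  intra <- sum(lengths(lapply(unique(small$node_labels), function(nw)
    intra_network_edge_indices(small, nw))))
  tal <- network_tally(seq_len(n_edges(30)), small)
  expect_identical(sum(diag(tal)), as.integer(intra))
  expect_identical(sum(tal), n_edges(30))
})

test_that("scaled atlas preserves canonical proportions and totals", {
  a40 <- scaled_atlas(40)
  expect_identical(a40$node_count, 40L)
  expect_identical(sort(unique(a40$node_labels)),
                   sort(names(canonical_network_sizes())))
  expect_identical(scaled_atlas(268)$node_labels,
                   canonical_atlas()$node_labels)
})

test_that("file ingestion round-trips time series, matrices and atlases", {
  tmp <- withr::local_tempdir()
  ts <- matrix(rnorm(40), 10, 4,
               dimnames = list(NULL, paste0("roi", 1:4)))
  f <- file.path(tmp, "run1.tsv")
  write.table(ts, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(unname(read_timeseries(f)), unname(ts), tolerance = 1e-12)
  m <- sym_matrix(5)
  f2 <- file.path(tmp, "fc.tsv")
  write.table(m, f2, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_equal(read_fc_matrix(f2), m, tolerance = 1e-12)
  atl <- scaled_atlas(20)
  f3 <- file.path(tmp, "atlas.tsv")
  write_atlas(atl, f3)
  expect_identical(read_atlas(f3)$node_labels, atl$node_labels)
})
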