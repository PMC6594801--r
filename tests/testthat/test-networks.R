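test_that("functional network equals brute-force Pearson and obeys policy", {
  ts <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  net <- build_functional_network(ts)
  expect_equal(net["a", "b"], 1)          # perfect correlation
  expect_equal(net["a", "c"], 0)          # r = -1 zeroed
  net_abs <- build_functional_network(ts, "absolute")
  expect_equal(net_abs["a", "c"], 1)

  set.seed(3)
  ts <- matrix(rnorm(250), 50, 5)
  net <- build_functional_network(ts)
  # covariance-based oracle
  for (i in 1:4) for (j in (i + 1):5) {
    r <- cov(ts[, i], ts[, j]) / (sd(ts[, i]) * sd(ts[, j]))
    expect_equal(net[i, j], max(r, 0), tolerance = 1e-12)
  }
  expect_true(all(diag(unclass(net)) == 0))
})

test_that("functional network is invariant to affine rescaling of a region", {
  set.seed(4)
  ts <- matrix(rnorm(200), 40, 5)
  ts2 <- ts
  ts2[, 3] <- 5 - 2.5 * ts2[, 3]   # negative slope flips sign of its edges
  n1 <- build_functional_network(ts, "absolute")
  n2 <- build_functional_network(ts2, "absolute")
  expect_equal(unclass(n1), unclass(n2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degenerate time series are rejected", {
  ts <- cbind(a = c(1, 2, 3), b = c(2, 2, 2))
  expect_error(build_functional_network(ts), "b")
  ts[2, 1] <- NA
  expect_error(build_functional_network(ts), "non-finite")
  expect_error(build_functional_network(matrix(1, 1, 2)), "2 timepoints")
})

test_that("structural normalization divides counts by the volume sum", {
  atlas <- region_atlas(c("x.L", "y.R"), c("L", "R"), c(FALSE, FALSE), c(2, 3))
  counts <- matrix(c(0, 10, 10, 0), 2)
  net <- build_structural_network(counts, atlas)
  expect_equal(net["x.L", "y.R"], 2)
  expect_equal(build_structural_network(matrix(0, 2, 2), atlas)["x.L", "y.R"], 0)

  # scale covariance: doubling volumes halves weights; symmetry preserved
  set.seed(5)
  atlas6 <- teanet:::toy_atlas(6)
  counts <- matrix(0L, 6, 6)
  up <- upper.tri(counts)
  counts[up] <- rpois(sum(up), 20)
  counts <- counts + t(counts)
  n1 <- build_structural_network(counts, atlas6)
  atlas2 <- atlas6; atlas2$volume <- 2 * atlas2$volume
  n2 <- build_structural_network(counts, atlas2)
  expect_equal(unclass(n1), 2 * unclass(n2), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(unclass(n1), t(unclass(n1)))
})

test_that("structural construction validates its inputs", {
  atlas <- teanet:::toy_atlas(4)
  expect_error(build_structural_network(matrix(0, 3, 3), atlas), "atlas has 4")
  bad <- matrix(0L, 4, 4); bad[1, 2] <- 3L   # asymmetric
  expect_error(build_structural_network(bad, atlas), "symmetric")
})

test_that("sparsity thresholding keeps exactly K largest edges", {
  set.seed(6)
  m <- random_weight_matrix(8, density = 1)
  for (s in c(0.1, 0.25, 0.5, 0.8)) {
    k <- floor(s * 28 + 0.5)
    thr <- apply_sparsity_threshold(m, s)
    expect_equal(sum(thr[upper.tri(thr)] > 0), k)
    # retained weights are the K largest, values unchanged
    kept <- sort(thr[upper.tri(thr)][thr[upper.tri(thr)] > 0], decreasing = TRUE)
    expect_equal(kept, sort(m[upper.tri(m)], decreasing = TRUE)[1:k])
  }
  expect_identical(apply_sparsity_threshold(m, 1), m)
  expect_error(apply_sparsity_threshold(m, 0), "sparsity")
  expect_error(apply_sparsity_threshold(m, 1.2), "sparsity")
})

test_that("equal-weight ties break by ascending (row, column)", {
  m <- matrix(1, 4, 4); diag(m) <- 0
  thr <- apply_sparsity_threshold(m, 0.5)   # K = 3 of 6
  expect_equal(sum(thr[upper.tri(thr)] > 0), 3)
  expect_equal(thr[1, 2], 1); expect_equal(thr[1, 3], 1); expect_equal(thr[1, 4], 1)
  expect_equal(thr[2, 3], 0); expect_equal(thr[2, 4], 0); expect_equal(thr[3, 4], 0)
})

test_that("thresholding is idempotent and edge sets nest across levels", {
  set.seed(8)
  for (rep in 1:5) {
    m <- random_weight_matrix(10, density = 0.9)
    prev_edges <- NULL
    for (s in c(0.1, 0.2, 0.3, 0.4)) {
      thr <- apply_sparsity_threshold(m, s)
      expect_equal(unclass(apply_sparsity_threshold(thr, s)), unclass(thr))
      edges <- which(thr[upper.tri(thr)] > 0)
      if (!is.null(prev_edges)) expect_true(all(prev_edges %in% edges))
      prev_edges <- edges
    }
  }
})

test_that("builders satisfy connectivity-matrix invariants on random input", {
  set.seed(9)
  atlas <- teanet:::toy_atlas(10)
  for (rep in 1:10) {
    ts <- matrix(rnorm(30 * 10), 30, 10)
    colnames(ts) <- atlas$label
    fn <- build_functional_network(ts)
    expect_silent(validate_connectivity(fn))
    counts <- matrix(0L, 10, 10)
    up <- upper.tri(counts)
    counts[up] <- rpois(sum(up), 5)
    counts <- counts + t(counts)
    sn <- build_structural_network(counts, atlas)
    expect_silent(validate_connectivity(sn))
  }
})

test_that("matrix and time-series TSV round-trips are exact", {
  dir <- withr::local_tempdir()
  atlas <- teanet:::toy_atlas(6)
  m <- matrix(runif(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(atlas$label, atlas$label)
  p <- file.path(dir, "m.tsv")
  write_matrix_tsv(m, p)
  expect_equal(read_matrix_tsv(p), m, tolerance = 1e-12)

  ts <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, atlas$label))
  tp <- file.path(dir, "ts.tsv")
  write.table(ts, tp, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_timeseries(tp, atlas)
  expect_equal(back, ts, tolerance = 1e-12)
})
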