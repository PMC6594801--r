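test_that("permutation test enumerates exhaustively on small fixtures", {
  r <- permutation_test(c(0, 0, 0), c(1, 1, 1))
  expect_true(r$exact)
  expect_equal(r$n_perm, 20)            # all 6-choose-3 label splits
  expect_equal(r$p, 0.1)                # only the true split and its mirror
  expect_equal(r$observed_diff, -1)

  tied <- permutation_test(c(2, 2), c(2, 2))
  expect_equal(tied$p, 1)
  expect_equal(tied$observed_diff, 0)
  expect_error(permutation_test(1, c(1, 2)), "2 subjects")
})

test_that("sampled p converges to the exhaustive p and is reproducible", {
  a <- c(0.1, 0.4, 0.9); b <- c(1.2, 1.5, 1.1)
  exact <- permutation_test(a, b, method = "exhaustive")$p
  ps <- sapply(c(200, 2000, 20000), function(np) {
    permutation_test(a, b, n_perm = np, seed = 5, method = "sample")$p
  })
  expect_lt(abs(ps[3] - exact), abs(ps[1] - exact) + 0.05)
  expect_lt(abs(ps[3] - exact), 0.02)
  # bit-for-bit reproducibility at fixed seed; swap symmetry
  r1 <- permutation_test(a, b, n_perm = 500, seed = 9, method = "sample")
  r2 <- permutation_test(a, b, n_perm = 500, seed = 9, method = "sample")
  expect_identical(r1, r2)
  r3 <- permutation_test(b, a, n_perm = 500, seed = 9, method = "sample")
  expect_equal(r3$observed_diff, -r1$observed_diff)
  expect_equal(r3$p, r1$p)
})

test_that("sampled p-values respect the +1/+1 floor", {
  set.seed(30)
  a <- rnorm(10) + 100; b <- rnorm(10)
  r <- permutation_test(a, b, n_perm = 99, seed = 1, method = "sample")
  expect_equal(r$p, 1 / 100)
  expect_gte(r$p, 1 / (r$n_perm + 1))
})

test_that("BH-FDR matches hand-evaluated vectors and brute force", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(0.005, 0.04, 0.6)), c(0.015, 0.06, 0.6))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")

  set.seed(31)
  for (rep in 1:1000) {
    p <- runif(sample(1:12, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))           # q >= p
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p
  }
})

test_that("global-metric comparison corrects within the 4-metric family", {
  set.seed(32)
  X <- matrix(rnorm(10 * 4), 10, 4,
              dimnames = list(NULL, c("C_w", "L_w", "E_loc", "E_glob")))
  groups <- rep(c("T", "NT"), each = 5)
  res <- compare_global_metrics(X, groups, n_perm = 200, seed = 3)
  expect_equal(nrow(res), 4)
  expect_equal(res$q, bh_fdr(res$p))
  # swapping labels negates the difference, keeps p
  res2 <- compare_global_metrics(X, rev(groups), n_perm = 200, seed = 3)
  expect_equal(res2$observed_diff, -res$observed_diff)
  expect_equal(res2$p, res$p)
  X[2, 3] <- NA
  expect_error(compare_global_metrics(X, groups), "missing")
})

test_that("nodal comparison is exploratory and constant regions give p = 1", {
  X <- matrix(5, 8, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  res <- compare_nodal_efficiency(X, rep(c("T", "NT"), 4), n_perm = 50, seed = 2)
  expect_true(all(res$p == 1))
  expect_true(all(is.na(res$q)))
  expect_true(all(res$exploratory))
})

test_that("asymmetry comparison drops undefined indices with a warning", {
  set.seed(33)
  X <- matrix(rnorm(12 * 4), 12, 4,
              dimnames = list(NULL, c("C_w", "L_w", "E_loc", "E_glob")))
  X[1, 2] <- NA
  groups <- rep(c("T", "NT"), each = 6)
  expect_warning(res <- compare_asymmetry(X, groups, n_perm = 100, seed = 4),
                 "dropped")
  expect_equal(nrow(res), 4)
  expect_equal(res$q, bh_fdr(res$p))
})

test_that("DMN edge comparison tests exactly the flagged pairs", {
  atlas <- teanet:::toy_atlas(16)    # 14 DMN regions flagged
  expect_equal(sum(atlas$dmn), 14)
  set.seed(34)
  nets <- lapply(1:8, function(s) {
    m <- random_weight_matrix(16, density = 1)
    dimnames(m) <- list(atlas$label, atlas$label)
    m
  })
  groups <- rep(c("T", "NT"), each = 4)
  res <- compare_dmn_edges(nets, groups, atlas, n_perm = 60, seed = 5)
  expect_equal(nrow(res), 91)        # 14 * 13 / 2 candidate edges
  expect_true(all(res$region_a %in% atlas$label[atlas$dmn]))
  # observed difference equals group mean difference of the raw weights
  i <- which(atlas$label == res$region_a[1]); j <- which(atlas$label == res$region_b[1])
  w <- sapply(nets, function(m) m[i, j])
  expect_equal(res$observed_diff[1], mean(w[1:4]) - mean(w[5:8]))
  noatlas <- atlas; noatlas$dmn <- FALSE
  expect_error(compare_dmn_edges(nets, groups, noatlas), "no DMN")
})

test_that("type-I error of the permutation test is nominal under the null", {
  # Monte-Carlo calibration: both groups from one distribution
  set.seed(35)
  n_rep <- 400
  rej <- 0
  for (r in 1:n_rep) {
    x <- rnorm(6); y <- rnorm(8)
    p <- permutation_test(x, y, n_perm = 200, seed = r, method = "sample")$p
    rej <- rej + (p < 0.05)
  }
  # exact binomial 95% acceptance interval around 0.05 for 400 draws
  expect_gte(rej, qbinom(0.025, n_rep, 0.05))
  expect_lte(rej, qbinom(0.975, n_rep, 0.05))
})
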