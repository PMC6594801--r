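# closed-form fixtures -------------------------------------------------

path3 <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w
}

complete_graph <- function(n, w = 1) {
  m <- matrix(w, n, n); diag(m) <- 0; m
}

star_graph <- function(leaves) {
  n <- leaves + 1
  m <- matrix(0, n, n)
  m[1, 2:n] <- m[2:n, 1] <- 1
  m
}

test_that("distances follow the 1/w length map", {
  w <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(to_distance(w)[1, 2], 2)
  d <- to_distance(path3())
  expect_equal(d[1, 3], 2)
  expect_equal(diag(d), rep(0, 3))
})

test_that("closed-form global metrics are exact", {
  k4 <- complete_graph(4)
  d4 <- to_distance(k4)
  expect_equal(global_efficiency(d4), 1)
  expect_equal(as.numeric(characteristic_path_length(d4)), 1)
  expect_equal(weighted_clustering(k4), 1)
  expect_equal(local_efficiency(k4), 1)

  dp <- to_distance(path3())
  expect_equal(global_efficiency(dp), 5 / 6)
  expect_equal(as.numeric(characteristic_path_length(dp)), 4 / 3)
  expect_equal(weighted_clustering(path3()), 0)

  # star: hub nodal efficiency 1, leaves 2/3; leaves pairwise unconnected
  s <- star_graph(3)
  ds <- to_distance(s)
  expect_equal(nodal_efficiency(ds, 1), 1)
  expect_equal(nodal_efficiency(ds, 2), 2 / 3)
  expect_equal(local_efficiency(s), 0)

  # edgeless: efficiency 0, path length undefined
  e <- matrix(0, 4, 4)
  expect_equal(global_efficiency(to_distance(e)), 0)
  expect_error(characteristic_path_length(to_distance(e)), "disconnected")
  # isolated node has nodal efficiency 0
  m <- complete_graph(4); m[4, ] <- m[, 4] <- 0
  expect_equal(unname(nodal_efficiency(to_distance(m), 4)), 0)
})

test_that("disconnected pairs are excluded from L_w and counted", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 0.5
  lw <- characteristic_path_length(to_distance(m))
  expect_equal(as.numeric(lw), mean(c(1, 2)))
  expect_equal(attr(lw, "n_disconnected_pairs"), 4L)
})

test_that("every metric matches brute-force oracles on random graphs", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    w <- random_weight_matrix(n, density = runif(1, 0.3, 1))
    d <- to_distance(w)
    expect_equal(unname(d), oracle_distance(w), tolerance = 1e-12)
    expect_equal(global_efficiency(d), oracle_global_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(unname(nodal_efficiency(d)), oracle_nodal_efficiency(w),
                 tolerance = 1e-10)
    if (any(is.finite(d[upper.tri(d)]))) {
      expect_equal(as.numeric(characteristic_path_length(d)),
                   oracle_char_path_length(w), tolerance = 1e-10)
    }
    expect_equal(weighted_clustering(w), oracle_onnela_clustering(w),
                 tolerance = 1e-10)
    expect_equal(local_efficiency(w), oracle_local_efficiency(w),
                 tolerance = 1e-10)
  }
})

test_that("weighted triangle clustering matches direct triple enumeration", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 1
  w[2, 3] <- w[3, 2] <- 0.125
  # every node has one closed triangle; normalized weights are w/max = w
  c1 <- (1 * 1 * 0.125)^(1 / 3)      # node 1: edges 1, 1, opposite 0.125
  c2 <- (1 * 0.125 * 1)^(1 / 3)
  c3 <- (1 * 0.125 * 1)^(1 / 3)
  expect_equal(weighted_clustering(w), mean(c(c1, c2, c3)), tolerance = 1e-12)
  expect_equal(weighted_clustering(w), oracle_onnela_clustering(w),
               tolerance = 1e-12)
})

test_that("scale property: weights scale distances and efficiencies, not C_w", {
  set.seed(12)
  w <- random_weight_matrix(9, density = 0.7)
  lam <- 3.7
  d1 <- to_distance(w); d2 <- to_distance(lam * w)
  fin <- is.finite(d1)
  expect_equal(d2[fin], d1[fin] / lam, tolerance = 1e-10)
  expect_equal(global_efficiency(d2), lam * global_efficiency(d1),
               tolerance = 1e-10)
  expect_equal(unname(nodal_efficiency(d2)), lam * unname(nodal_efficiency(d1)),
               tolerance = 1e-10)
  expect_equal(weighted_clustering(lam * w), weighted_clustering(w),
               tolerance = 1e-12)
})

test_that("relabeling nodes permutes nodal efficiency, fixes global metrics", {
  set.seed(13)
  w <- random_weight_matrix(8, density = 0.8)
  perm <- sample(8)
  wp <- w[perm, perm]
  expect_equal(unname(nodal_efficiency(to_distance(wp))),
               unname(nodal_efficiency(to_distance(w)))[perm],
               tolerance = 1e-10)
  expect_equal(weighted_clustering(wp), weighted_clustering(w), tolerance = 1e-10)
  expect_equal(local_efficiency(wp), local_efficiency(w), tolerance = 1e-10)
  expect_equal(global_efficiency(to_distance(wp)),
               global_efficiency(to_distance(w)), tolerance = 1e-10)
})

test_that("Barrat clustering variant agrees with its own brute force", {
  oracle_barrat <- function(w) {
    n <- nrow(w); a <- (w > 0) * 1
    ci <- numeric(n)
    for (i in seq_len(n)) {
      k <- sum(a[i, ]); s <- sum(w[i, ])
      if (k < 2 || s == 0) next
      tot <- 0
      for (j in seq_len(n)) for (h in seq_len(n)) {
        if (j != i && h != i && j != h && a[i, j] && a[i, h] && a[j, h]) {
          tot <- tot + (w[i, j] + w[i, h]) / 2
        }
      }
      ci[i] <- tot / (s * (k - 1))
    }
    mean(ci)
  }
  set.seed(14)
  for (rep in 1:20) {
    w <- random_weight_matrix(8, density = 0.7)
    expect_equal(weighted_clustering(w, "barrat"), oracle_barrat(w),
                 tolerance = 1e-10)
  }
  # unit-weight complete graph: both formulations give 1
  expect_equal(weighted_clustering(complete_graph(5), "barrat"), 1)
})

test_that("sweep integrates by the trapezoid rule over 31 levels", {
  set.seed(15)
  w <- random_weight_matrix(12, density = 1)
  sw <- sweep_and_integrate(w)
  expect_length(sw$levels, 31)
  expect_equal(sw$levels[1], 0.1)
  expect_equal(sw$levels[31], 0.4)
  # independent trapezoid re-summation
  for (m in c("C_w", "L_w", "E_loc", "E_glob")) {
    y <- sw$per_level[[m]]
    manual <- sum(diff(sw$levels) * (y[-31] + y[-1]) / 2)
    expect_equal(sw$integrated[[m]], manual, tolerance = 1e-12)
  }
  # E_glob is non-decreasing in sparsity
  expect_true(all(diff(sw$per_level$E_glob) >= -1e-12))
})

test_that("constant metric integrates to value times interval width", {
  # complete unit graph: all subgraphs at sparsity >= needed stay... not
  # constant; instead check the rule directly through a linear case and
  # the trapezoid helper on a constant vector
  lv <- seq(0.1, 0.4, 0.01)
  expect_equal(teanet:::trapezoid(lv, rep(1, 31)), 0.3)
  expect_equal(teanet:::trapezoid(lv, rep(2.5, 31)), 0.75)
  expect_error(sweep_and_integrate(complete_graph(5), 0.4, 0.1), "grid")
})

test_that("E_glob monotonicity holds across the sweep on random inputs", {
  set.seed(16)
  for (rep in 1:5) {
    w <- random_weight_matrix(15, density = 0.9)
    sw <- sweep_and_integrate(w, 0.1, 0.4, 0.05)
    expect_true(all(diff(sw$per_level$E_glob) >= -1e-12))
  }
})
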