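# Independent brute-force reference implementations used as oracles.
# Deliberately naive: triple loops and direct definitions, no shared code
# with the package internals.

# Floyd-Warshall all-pairs shortest paths on a length matrix (Inf = absent)
oracle_floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_distance <- function(w) {
  len <- ifelse(w > 0, 1 / w, Inf)
  oracle_floyd_warshall(len)
}

oracle_global_efficiency <- function(w) {
  d <- oracle_distance(w)
  n <- nrow(w)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

oracle_nodal_efficiency <- function(w) {
  d <- oracle_distance(w)
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    s / (n - 1)
  })
}

oracle_char_path_length <- function(w) {
  d <- oracle_distance(w)
  vals <- c()
  n <- nrow(w)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.finite(d[i, j])) vals <- c(vals, d[i, j])
  }
  mean(vals)
}

# Onnela clustering by exhaustive ordered-triple enumeration
oracle_onnela_clustering <- function(w) {
  n <- nrow(w)
  if (max(w) == 0) return(0)
  wh <- w / max(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    tot <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        tot <- tot + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    ci[i] <- tot / (k * (k - 1))
  }
  mean(ci)
}

# local efficiency by per-node neighbor-subgraph recomputation
oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    eff[i] <- oracle_global_efficiency(w[nb, nb, drop = FALSE])
  }
  mean(eff)
}

# BH step-up by the definition q_(i) = min_{j>=i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- sapply(seq_len(m), function(i) {
    min(sapply(i:m, function(j) ps[j] * m / j))
  })
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# random symmetric nonnegative weight matrix, zero diagonal; some zero
# entries so disconnection and degree-1 nodes occur
random_weight_matrix <- function(n, density = 0.6, max_w = 1) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- sample(c(TRUE, FALSE), length(up), replace = TRUE,
               prob = c(density, 1 - density))
  w[up[on]] <- runif(sum(on), 0.05, max_w)
  w + t(w)
}
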