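# Weighted graph metrics: shortest-path distances, efficiencies, clustering,
# and their integration over a sparsity-threshold sweep.
#
# Conventions (recorded in sweep output metadata):
#  * weight -> length map is 1/w; absent edges have infinite length
#  * clustering is Onnela's geometric-mean-of-triangles form, with weights
#    normalized by the network maximum (Barrat's form available)
#  * pairs with no connecting path are excluded from L_w's mean (count
#    reported via attribute); efficiencies treat them natively as 1/Inf = 0

as_weight_matrix <- function(net) {
  mat <- unclass(net)
  attr(mat, "subject_id") <- NULL
  attr(mat, "modality") <- NULL
  mat
}

#' Shortest-path distance matrix of a weighted network
#'
#' Edge length is the reciprocal of edge weight (strong connections are
#' short); absent edges are infinitely long. All-pairs shortest paths are
#' computed by Dijkstra's algorithm on the length graph.
#'
#' @param net symmetric nonnegative weight matrix.
#' @return symmetric distance matrix with zero diagonal; `Inf` marks
#'   disconnected pairs.
#' @export
to_distance <- function(net) {
  w <- as_weight_matrix(net)
  if (any(w < 0)) stop_teanet("weights must be nonnegative")
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Global efficiency
#'
#' Mean over all ordered pairs i != j of the inverse shortest-path distance,
#' with disconnected pairs contributing 0.
#'
#' @param d distance matrix from [to_distance()].
#' @return scalar in \[0, 1\] for networks with maximum weight <= 1.
#' @export
global_efficiency <- function(d) {
  n <- nrow(d)
  if (n < 2) stop_teanet("global efficiency needs at least 2 nodes")
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' For region i: the mean inverse distance from i to every other region,
#' `(1/(N-1)) * sum_j 1/d(i,j)`. Vectorized over all regions when `i` is
#' omitted.
#'
#' @param d distance matrix.
#' @param i region index (optional; default all regions).
#' @return scalar, or the length-N vector of nodal efficiencies.
#' @export
nodal_efficiency <- function(d, i = NULL) {
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  eff <- rowSums(inv) / (n - 1)
  names(eff) <- rownames(d)
  if (is.null(i)) return(eff)
  if (i < 1 || i > n) stop_teanet("region index out of range")
  eff[[i]]
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal shortest-path distances. Disconnected
#' pairs are excluded from the mean; their count is attached as attribute
#' `n_disconnected_pairs` (unordered pairs).
#'
#' @param d distance matrix.
#' @return scalar with attribute `n_disconnected_pairs`.
#' @export
characteristic_path_length <- function(d) {
  off <- d[upper.tri(d)]
  fin <- off[is.finite(off)]
  if (!length(fin)) stop_teanet("characteristic path length undefined: network fully disconnected")
  structure(mean(fin), n_disconnected_pairs = sum(!is.finite(off)))
}

#' Weighted clustering coefficient
#'
#' Onnela formulation (default): weights are normalized by the network
#' maximum, and for every node with degree k >= 2 the geometric mean of
#' triangle weights is averaged over the k(k-1) ordered neighbor pairs;
#' nodes with k < 2 contribute 0; C_w is the mean over nodes. The Barrat
#' formulation (arithmetic weight of closed triangles relative to node
#' strength) is available as an alternative.
#'
#' @param net symmetric nonnegative weight matrix.
#' @param method `"onnela"` (default) or `"barrat"`.
#' @return scalar C_w >= 0 (<= 1 for Onnela).
#' @export
weighted_clustering <- function(net, method = c("onnela", "barrat")) {
  method <- match.arg(method)
  w <- as_weight_matrix(net)
  if (any(w < 0)) stop_teanet("weights must be nonnegative")
  a <- (w > 0) * 1
  k <- rowSums(a)
  if (max(w) == 0) return(0)
  ci <- numeric(nrow(w))
  if (method == "onnela") {
    wh <- (w / max(w))^(1 / 3)
    num <- diag(wh %*% wh %*% wh)   # sum over ordered (j,h) of cube-root products
    ok <- k >= 2
    ci[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  } else {
    s <- rowSums(w)
    # per node: sum over neighbor pairs (j,h) closing a triangle of (w_ij+w_ih)/2
    n <- nrow(w)
    num <- vapply(seq_len(n), function(i) {
      nb <- which(a[i, ] > 0)
      if (length(nb) < 2) return(0)
      sub <- a[nb, nb, drop = FALSE]
      wij <- w[i, nb]
      sum(outer(wij, wij, `+`) / 2 * sub)
    }, numeric(1))
    ok <- k >= 2 & s > 0
    ci[ok] <- num[ok] / (s[ok] * (k[ok] - 1))
  }
  mean(ci)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subnetwork induced by
#' each node's neighbors, keeping the original edge weights on that subset.
#' Nodes with fewer than two neighbors contribute 0.
#'
#' @param net symmetric nonnegative weight matrix.
#' @return scalar E_loc >= 0.
#' @export
local_efficiency <- function(net) {
  w <- as_weight_matrix(net)
  if (nrow(w) < 2) stop_teanet("local efficiency needs at least 2 nodes")
  if (any(w < 0)) stop_teanet("weights must be nonnegative")
  n <- nrow(w)
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(to_distance(w[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(eff)
}

#' All global metrics of one network
#'
#' @param net symmetric nonnegative weight matrix.
#' @param clustering_method passed to [weighted_clustering()].
#' @return list with `C_w`, `L_w`, `E_loc`, `E_glob`, `nodal` (vector) and
#'   `n_disconnected_pairs`.
#' @export
global_metrics <- function(net, clustering_method = "onnela") {
  d <- to_distance(net)
  lw <- characteristic_path_length(d)
  list(
    C_w = weighted_clustering(net, clustering_method),
    L_w = as.numeric(lw),
    E_loc = local_efficiency(net),
    E_glob = global_efficiency(d),
    nodal = nodal_efficiency(d),
    n_disconnected_pairs = attr(lw, "n_disconnected_pairs")
  )
}

# trapezoid rule on an arbitrary strictly-increasing grid
trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Sparsity sweep with trapezoid integration
#'
#' Thresholds the network at each sparsity level of a regular grid (default
#' 0.10 to 0.40 in steps of 0.01, 31 levels), computes all global metrics at
#' every level, and integrates each metric over sparsity by the trapezoid
#' rule. A metric constant at c over \[0.1, 0.4\] integrates to 0.3 c.
#'
#' @param net connectivity matrix (nonnegative weights).
#' @param s_min,s_max,step sweep grid; defaults 0.1, 0.4, 0.01.
#' @param clustering_method passed to [weighted_clustering()].
#' @return list with `levels` (grid), `per_level` (data frame of the four
#'   global metrics per level), `nodal_per_level` (levels x regions matrix),
#'   `integrated` (named list: the four metrics plus `nodal` vector).
#' @export
sweep_and_integrate <- function(net, s_min = 0.1, s_max = 0.4, step = 0.01,
                                clustering_method = "onnela") {
  if (!(s_min > 0 && s_min < s_max && s_max <= 1 && step > 0)) {
    stop_teanet("invalid sweep grid: need 0 < s_min < s_max <= 1 and step > 0")
  }
  levels <- seq(s_min, s_max, by = step)
  if (length(levels) < 2) stop_teanet("sweep grid must have at least 2 levels")
  per <- vector("list", length(levels))
  nodal <- NULL
  for (j in seq_along(levels)) {
    m <- global_metrics(apply_sparsity_threshold(net, levels[j]),
                        clustering_method)
    per[[j]] <- data.frame(sparsity = levels[j], C_w = m$C_w, L_w = m$L_w,
                           E_loc = m$E_loc, E_glob = m$E_glob)
    if (is.null(nodal)) {
      nodal <- matrix(NA_real_, length(levels), length(m$nodal),
                      dimnames = list(NULL, names(m$nodal)))
    }
    nodal[j, ] <- m$nodal
  }
  per_level <- do.call(rbind, per)
  integrated <- lapply(c(C_w = "C_w", L_w = "L_w", E_loc = "E_loc",
                         E_glob = "E_glob"),
                       function(v) trapezoid(levels, per_level[[v]]))
  integrated$nodal <- apply(nodal, 2, function(y) trapezoid(levels, y))
  list(levels = levels, per_level = per_level, nodal_per_level = nodal,
       integrated = integrated)
}
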