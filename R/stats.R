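# Permutation-based group inference with Benjamini-Hochberg FDR control.
#
# The test statistic is the difference of group means (T minus NT),
# two-sided via its absolute value; a t-statistic variant is available.
# Sampled permutations use the +1/+1 convention so p >= 1/(n_perm + 1);
# when the label space is small enough the test enumerates exhaustively and
# the p-value is exact.

# Permutation engine shared by all compare_* functions. X: subjects x
# variables matrix; grp_a: logical vector marking group a. Returns observed
# differences and two-sided p-values, all variables sharing one set of
# label permutations.
perm_engine <- function(X, grp_a, n_perm = 10000, seed = 1,
                        method = c("auto", "sample", "exhaustive"),
                        statistic = c("mean_diff", "t")) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  X <- as.matrix(X)
  check_finite(X, "values")
  n <- nrow(X)
  na <- sum(grp_a)
  nb <- n - na
  if (na < 2 || nb < 2) stop_teanet("each group needs at least 2 subjects")
  stat_fun <- function(a_idx) {
    inb <- setdiff(seq_len(n), a_idx)
    ma <- colMeans(X[a_idx, , drop = FALSE])
    mb <- colMeans(X[inb, , drop = FALSE])
    if (statistic == "mean_diff") return(ma - mb)
    va <- apply(X[a_idx, , drop = FALSE], 2, stats::var)
    vb <- apply(X[inb, , drop = FALSE], 2, stats::var)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    out <- (ma - mb) / se
    out[se == 0 & ma == mb] <- 0
    out
  }
  obs <- stat_fun(which(grp_a))
  n_assign <- choose(n, na)
  exhaustive <- method == "exhaustive" ||
    (method == "auto" && n_assign <= n_perm)
  if (exhaustive) {
    combos <- utils::combn(n, na)
    null_abs <- apply(combos, 2, function(ix) abs(stat_fun(ix)))
    if (is.null(dim(null_abs))) null_abs <- matrix(null_abs, nrow = 1)
    p <- rowMeans(null_abs >= abs(obs) - 1e-12)  # recycles per column
    list(observed = obs, p = p, n_perm = ncol(combos), exact = TRUE)
  } else {
    p_count <- with_seed(seed, {
      cnt <- numeric(ncol(X))
      for (b in seq_len(n_perm)) {
        ix <- sample.int(n, na)
        cnt <- cnt + (abs(stat_fun(ix)) >= abs(obs) - 1e-12)
      }
      cnt
    })
    list(observed = obs, p = (1 + p_count) / (1 + n_perm),
         n_perm = n_perm, exact = FALSE)
  }
}

#' Two-sided permutation test for a group difference
#'
#' The statistic is the difference of group means (a minus b). The null
#' distribution comes from random reassignments of group labels; when the
#' number of distinct assignments is at most `n_perm` the test enumerates
#' all of them and the p-value is exact (no +1 correction); otherwise
#' `n_perm` assignments are sampled and `p = (1 + #{|d*| >= |d_obs|}) /
#' (1 + n_perm)`.
#'
#' @param values_a,values_b numeric vectors (>= 2 finite values each).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the label shuffles.
#' @param method `"auto"` (default; enumerate when feasible), `"sample"`, or
#'   `"exhaustive"`.
#' @param statistic `"mean_diff"` (default) or `"t"` (pooled t inside the
#'   permutation scheme; p-values are typically very close).
#' @return list: `observed_diff`, `p`, `n_perm` (assignments evaluated),
#'   `exact`, `seed`.
#' @export
permutation_test <- function(values_a, values_b, n_perm = 10000, seed = 1,
                             method = c("auto", "sample", "exhaustive"),
                             statistic = c("mean_diff", "t")) {
  x <- c(values_a, values_b)
  grp <- c(rep(TRUE, length(values_a)), rep(FALSE, length(values_b)))
  r <- perm_engine(matrix(x, ncol = 1), grp, n_perm, seed, method, statistic)
  list(observed_diff = unname(r$observed), p = unname(r$p),
       n_perm = r$n_perm, exact = r$exact, seed = seed)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up procedure: order p ascending, `q_(i) = min_(j>=i) p_(j) m / j`,
#' capped at 1, returned in the input order.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_teanet("p-values must lie in (0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# shared wrapper: permutation tests on the columns of X with BH correction
# across the column family (or none)
compare_matrix <- function(X, groups, n_perm, seed, fdr = TRUE,
                           statistic = "mean_diff") {
  grp_a <- groups == "T"
  if (!all(groups %in% c("T", "NT"))) {
    stop_teanet("groups must be 'T' or 'NT' (drop excluded subjects first)")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  r <- perm_engine(X, grp_a, n_perm, seed, statistic = statistic)
  out <- data.frame(
    variable = colnames(X),
    observed_diff = unname(r$observed),
    p = unname(r$p),
    n_perm = r$n_perm,
    seed = seed,
    row.names = NULL
  )
  out$q <- if (fdr) bh_fdr(out$p) else NA_real_
  out$exploratory <- !fdr
  out
}

#' Compare integrated global metrics between groups
#'
#' One permutation test per metric on the subjects' integrated (or plain,
#' for unthresholded networks) metric values; BH-FDR across the family of
#' four metrics within the modality.
#'
#' @param metrics subjects x 4 matrix with columns `C_w`, `L_w`, `E_loc`,
#'   `E_glob` (one modality).
#' @param groups `"T"`/`"NT"` per subject (row order of `metrics`).
#' @param n_perm,seed,statistic see [permutation_test()].
#' @return data frame: variable, observed_diff (T - NT), p, q, n_perm, seed.
#' @export
compare_global_metrics <- function(metrics, groups, n_perm = 10000, seed = 1,
                                   statistic = "mean_diff") {
  metrics <- as.matrix(metrics)
  if (any(is.na(metrics))) stop_teanet("missing metric value for some subject")
  compare_matrix(metrics, groups, n_perm, seed, fdr = TRUE, statistic)
}

#' Compare nodal efficiencies between groups (exploratory)
#'
#' One permutation test per region; reported uncorrected (`q = NA`,
#' `exploratory = TRUE`) for screening at p < 0.01, as regional analyses
#' here are hypothesis-generating.
#'
#' @param nodal subjects x regions matrix of (integrated) nodal
#'   efficiencies; column names are region labels.
#' @param groups,n_perm,seed,statistic see [compare_global_metrics()].
#' @return data frame, one row per region.
#' @export
compare_nodal_efficiency <- function(nodal, groups, n_perm = 10000, seed = 1,
                                     statistic = "mean_diff") {
  nodal <- as.matrix(nodal)
  if (any(is.na(nodal))) stop_teanet("missing nodal efficiency for some subject")
  compare_matrix(nodal, groups, n_perm, seed, fdr = FALSE, statistic)
}

#' Compare hemispheric asymmetry indices between groups
#'
#' One permutation test per metric on the subjects' asymmetry indices;
#' BH-FDR across the four metrics. Subjects whose index is undefined (`NA`)
#' for a metric are dropped from that metric's test with a warning.
#'
#' @param indices subjects x 4 matrix of asymmetry indices (columns `C_w`,
#'   `L_w`, `E_loc`, `E_glob`).
#' @param groups,n_perm,seed,statistic see [compare_global_metrics()].
#' @return data frame, one row per metric.
#' @export
compare_asymmetry <- function(indices, groups, n_perm = 10000, seed = 1,
                              statistic = "mean_diff") {
  indices <- as.matrix(indices)
  rows <- lapply(colnames(indices), function(v) {
    x <- indices[, v]
    keep <- !is.na(x)
    if (!all(keep)) {
      warning(sum(!keep), " subject(s) dropped from asymmetry test of ", v,
              " (undefined index)", call. = FALSE)
    }
    compare_matrix(matrix(x[keep], ncol = 1, dimnames = list(NULL, v)),
                   groups[keep], n_perm, seed, fdr = FALSE, statistic)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$exploratory <- FALSE
  out
}

#' Edge-wise comparison of default-mode-network connectivity
#'
#' Tests every unordered pair of DMN regions (91 edges for the 14-region
#' set) on raw, unthresholded connectivity strength. Uncorrected p-values,
#' flagged exploratory; significant edges are reported with the signed
#' group difference (T - NT).
#'
#' @param nets list of connectivity matrices (atlas order), one per subject.
#' @param groups `"T"`/`"NT"` per subject.
#' @param atlas a `region_atlas` with the DMN regions flagged.
#' @param n_perm,seed,statistic see [compare_global_metrics()].
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05, uncorrected).
#' @return data frame: region_a, region_b, observed_diff, p, significant,
#'   n_perm, seed.
#' @export
compare_dmn_edges <- function(nets, groups, atlas, n_perm = 10000, seed = 1,
                              statistic = "mean_diff", alpha = 0.05) {
  dmn_idx <- which(atlas$dmn)
  if (!length(dmn_idx)) stop_teanet("atlas flags no DMN regions")
  labels <- atlas$label[dmn_idx]
  pairs <- utils::combn(length(dmn_idx), 2)
  X <- t(vapply(nets, function(m) {
    sub <- unclass(m)[dmn_idx, dmn_idx, drop = FALSE]
    sub[cbind(pairs[1, ], pairs[2, ])]
  }, numeric(ncol(pairs))))
  colnames(X) <- paste(labels[pairs[1, ]], labels[pairs[2, ]], sep = "--")
  res <- compare_matrix(X, groups, n_perm, seed, fdr = FALSE, statistic)
  data.frame(
    region_a = labels[pairs[1, ]],
    region_b = labels[pairs[2, ]],
    observed_diff = res$observed_diff,
    p = res$p,
    significant = res$p < alpha,
    n_perm = res$n_perm,
    seed = seed,
    row.names = NULL
  )
}

#' Compare neuropsychological measures between groups
#'
#' One permutation test per measure with BH-FDR across the family of
#' measures (the 12 standard tests by default).
#'
#' @param cohort screened cohort data frame with a `group` column.
#' @param measures character vector of score column names.
#' @param n_perm,seed,statistic see [compare_global_metrics()].
#' @return data frame, one row per measure.
#' @export
compare_neuropsych <- function(cohort, measures, n_perm = 10000, seed = 1,
                               statistic = "mean_diff") {
  keep <- cohort$group %in% c("T", "NT")
  X <- as.matrix(cohort[keep, measures, drop = FALSE])
  compare_matrix(X, cohort$group[keep], n_perm, seed, fdr = TRUE, statistic)
}
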