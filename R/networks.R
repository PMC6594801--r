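# Construction of per-subject connectivity matrices and proportional
# (sparsity) thresholding.

#' Connectivity matrix container
#'
#' A square symmetric nonnegative matrix with zero diagonal, carrying the
#' subject id and modality as attributes. Node order is always atlas order;
#' row/column names are region labels when an atlas is attached.
#'
#' @param mat square numeric matrix.
#' @param subject_id subject identifier.
#' @param modality `"functional"` or `"structural"`.
#' @return matrix of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(mat, subject_id = NA_character_,
                                modality = c("functional", "structural")) {
  modality <- match.arg(modality)
  mat <- as.matrix(mat)
  attr(mat, "subject_id") <- as.character(subject_id)
  attr(mat, "modality") <- modality
  class(mat) <- c("connectivity_matrix", class(mat))
  validate_connectivity(mat)
}

#' @rdname connectivity_matrix
#' @export
validate_connectivity <- function(mat) {
  if (nrow(mat) != ncol(mat)) stop_teanet("connectivity matrix must be square")
  check_finite(mat, "connectivity matrix")
  if (max(abs(mat - t(mat))) > 1e-12) {
    stop_teanet("connectivity matrix must be symmetric (tolerance 1e-12)")
  }
  if (any(diag(mat) != 0)) stop_teanet("connectivity matrix diagonal must be 0")
  if (any(mat < 0)) stop_teanet("connectivity weights must be nonnegative")
  if (identical(attr(mat, "modality"), "functional") && any(mat > 1 + 1e-12)) {
    stop_teanet("functional connectivity weights must be <= 1")
  }
  mat
}

#' Functional connectivity from ROI time series
#'
#' Edge weight between two regions is the Pearson correlation of their
#' ROI-averaged time series. Negative correlations are zeroed (default) or
#' absolute-valued according to `negative_policy`; the diagonal is set to 0.
#'
#' @param ts numeric matrix, timepoints x regions; column names are region
#'   labels (atlas order).
#' @param negative_policy `"zero"` (default) or `"absolute"`.
#' @param subject_id subject identifier carried into the result.
#' @return a functional `connectivity_matrix`.
#' @export
build_functional_network <- function(ts, negative_policy = c("zero", "absolute"),
                                     subject_id = NA_character_) {
  negative_policy <- match.arg(negative_policy)
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop_teanet("time series needs at least 2 timepoints")
  check_finite(ts, "time series")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop_teanet("zero-variance time series for region(s): ",
                paste(bad, collapse = ", "))
  }
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -1), 1)           # guard rounding past +-1
  r <- switch(negative_policy, zero = pmax(r, 0), absolute = abs(r))
  diag(r) <- 0
  r <- (r + t(r)) / 2
  out <- connectivity_matrix(r, subject_id, "functional")
  attr(out, "negative_policy") <- negative_policy
  out
}

#' Structural connectivity from streamline counts
#'
#' Edge weight is the streamline count between two regions divided by the
#' sum of their volumes, removing the bias of larger regions accumulating
#' more streamlines. The normalization denominator (volume sum) is recorded
#' in the result's metadata.
#'
#' @param counts square symmetric matrix of nonnegative integer streamline
#'   counts with zero diagonal.
#' @param atlas a `region_atlas`; its `volume` column supplies the
#'   normalization and its size must match `counts`.
#' @param subject_id subject identifier.
#' @return a structural `connectivity_matrix`.
#' @export
build_structural_network <- function(counts, atlas, subject_id = NA_character_) {
  counts <- as.matrix(counts)
  n <- nrow(atlas)
  if (!all(dim(counts) == n)) {
    stop_teanet("streamline matrix is ", nrow(counts), "x", ncol(counts),
                " but atlas has ", n, " regions")
  }
  check_finite(counts, "streamline counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_teanet("streamline counts must be nonnegative integers")
  }
  if (max(abs(counts - t(counts))) > 0) stop_teanet("streamline matrix must be symmetric")
  if (any(atlas$volume <= 0)) stop_teanet("all region volumes must be positive")
  denom <- outer(atlas$volume, atlas$volume, `+`)
  w <- counts / denom
  diag(w) <- 0
  dimnames(w) <- list(atlas$label, atlas$label)
  out <- connectivity_matrix(w, subject_id, "structural")
  attr(out, "normalization") <- "volume_sum"
  out
}

# deterministic upper-triangle edge list ordered by descending weight,
# ties broken by ascending (row, column)
edge_order <- function(mat) {
  n <- nrow(mat)
  idx <- which(upper.tri(mat))
  row <- ((idx - 1) %% n) + 1
  col <- ((idx - 1) %/% n) + 1
  w <- mat[idx]
  o <- order(-w, row, col)
  list(idx = idx[o], row = row[o], col = col[o], w = w[o])
}

#' Proportional (sparsity) thresholding
#'
#' Retains the `K = round(s * N(N-1)/2)` largest-weight undirected edges
#' (round half away from zero) and zeroes the rest. Retained weights are
#' unchanged. Ties are broken deterministically by ascending (row, column)
#' index so that edge sets are nested across sparsity levels.
#'
#' @param net connectivity matrix (nonnegative weights).
#' @param sparsity fraction of possible edges to keep, in (0, 1].
#' @return thresholded matrix with the same attributes.
#' @export
apply_sparsity_threshold <- function(net, sparsity) {
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity > 1) {
    stop_teanet("sparsity must be in (0, 1]")
  }
  mat <- unclass(net)
  if (any(mat < 0)) stop_teanet("thresholding requires nonnegative weights")
  n <- nrow(mat)
  m <- n * (n - 1) / 2
  k <- round_half_up(sparsity * m)
  if (k >= m) return(net)
  eo <- edge_order(mat)
  keep <- eo$idx[seq_len(k)]
  out <- matrix(0, n, n, dimnames = dimnames(mat))
  out[keep] <- mat[keep]
  out <- out + t(out)
  attributes(out) <- utils::modifyList(attributes(mat),
                                       list(dim = dim(out), dimnames = dimnames(mat)))
  class(out) <- class(net)
  out
}

#' Read / write a dense labelled matrix as TSV
#'
#' Format: header row of region labels, then one row per region with the
#' label in the first column. Used for streamline counts and connectivity
#' matrices.
#'
#' @param path file path.
#' @return `read_matrix_tsv`: a labelled numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_matrix_tsv
#' @param mat matrix with row/column names.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(label = rownames(mat), as.data.frame(unclass(mat)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-subject ROI time series
#'
#' TSV/CSV with a header of atlas labels; rows are timepoints.
#'
#' @param path file path.
#' @param atlas optional `region_atlas`; when given, columns are checked and
#'   reordered to atlas order.
#' @return numeric matrix, timepoints x regions.
#' @export
read_timeseries <- function(path, atlas = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.csv(path, sep = sep, check.names = FALSE)
  mat <- as.matrix(df)
  if (!is.null(atlas)) {
    if (!setequal(colnames(mat), atlas$label)) {
      stop_teanet("time-series columns do not match atlas labels: ", path)
    }
    mat <- mat[, atlas$label, drop = FALSE]
  }
  mat
}
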