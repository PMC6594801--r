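# Hemispheric asymmetry: intra-hemispheric sub-networks and the laterality
# index (X_L - X_R) / (X_L + X_R); positive = leftward.

#' Split a network into intra-hemispheric sub-networks
#'
#' Inter-hemispheric connections are discarded and the two induced
#' sub-networks (one per hemisphere, atlas order preserved) are returned.
#' Hemisphere membership comes exclusively from the atlas.
#'
#' @param net connectivity matrix in atlas order.
#' @param atlas a `region_atlas` covering every node.
#' @return list with elements `left` and `right` (square matrices of equal
#'   size) and `provenance` (subject id and modality, if present).
#' @export
split_hemispheres <- function(net, atlas) {
  mat <- unclass(net)
  if (nrow(mat) != nrow(atlas)) {
    stop_teanet("network has ", nrow(mat), " nodes but atlas has ", nrow(atlas))
  }
  li <- which(atlas$hemisphere == "L")
  ri <- which(atlas$hemisphere == "R")
  if (length(li) != length(ri)) {
    stop_teanet("hemispheres have unequal sizes: ", length(li), " L vs ",
                length(ri), " R")
  }
  left <- mat[li, li, drop = FALSE]
  right <- mat[ri, ri, drop = FALSE]
  dimnames(left) <- list(atlas$label[li], atlas$label[li])
  dimnames(right) <- list(atlas$label[ri], atlas$label[ri])
  list(left = left, right = right,
       provenance = list(subject_id = attr(net, "subject_id"),
                         modality = attr(net, "modality")))
}

#' Hemispheric asymmetry (laterality) index
#'
#' `(x_left - x_right) / (x_left + x_right)`: +1 is fully leftward, -1 fully
#' rightward, 0 symmetric. Undefined when the denominator is zero; that case
#' returns `NA` with a warning so downstream comparisons can drop the
#' subject rather than treat it as symmetric.
#'
#' @param x_left,x_right metric value computed on each hemisphere.
#' @return index in \[-1, 1\] (for nonnegative inputs), or `NA`.
#' @export
asymmetry_index <- function(x_left, x_right) {
  denom <- x_left + x_right
  if (denom == 0) {
    warning("asymmetry undefined: X_L + X_R = 0; returning NA", call. = FALSE)
    return(NA_real_)
  }
  (x_left - x_right) / denom
}

#' Per-subject hemispheric asymmetry of global metrics
#'
#' Splits the network into hemispheres and computes the asymmetry index of
#' each global metric. For functional networks the sparsity sweep is applied
#' per sub-network (edge count from the 45-node sub-network's own possible
#' edges) and asymmetry is taken on the integrated metric values, keeping
#' the two hemispheres at matched density; structural networks are analyzed
#' unthresholded by default.
#'
#' @param net connectivity matrix (atlas order).
#' @param atlas a `region_atlas`.
#' @param sweep logical: sweep-and-integrate each hemisphere before
#'   comparing? Default `TRUE` for functional modality, else `FALSE`.
#' @param s_min,s_max,step sweep grid (used when `sweep` is `TRUE`).
#' @param clustering_method passed through to metric computation.
#' @return data frame: `metric`, `X_L`, `X_R`, `index`.
#' @export
hemisphere_asymmetry <- function(net, atlas,
                                 sweep = identical(attr(net, "modality"), "functional"),
                                 s_min = 0.1, s_max = 0.4, step = 0.01,
                                 clustering_method = "onnela") {
  halves <- split_hemispheres(net, atlas)
  metric_values <- function(m) {
    if (sweep) {
      sw <- sweep_and_integrate(m, s_min, s_max, step, clustering_method)
      unlist(sw$integrated[c("C_w", "L_w", "E_loc", "E_glob")])
    } else {
      g <- global_metrics(m, clustering_method)
      unlist(g[c("C_w", "L_w", "E_loc", "E_glob")])
    }
  }
  xl <- metric_values(halves$left)
  xr <- metric_values(halves$right)
  idx <- mapply(asymmetry_index, xl, xr)
  data.frame(metric = names(xl), X_L = unname(xl), X_R = unname(xr),
             index = unname(idx), row.names = NULL)
}
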