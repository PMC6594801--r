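# Region atlas: the single source of truth for node order, hemisphere
# membership, DMN membership and region volumes.

# Short codes of the 45 AAL cerebral parcels (one hemisphere), in template
# order. Regions alternate L/R in the full 90-node atlas (odd = left).
aal90_base_labels <- c(
  "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
  "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
  "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
  "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
  "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
  "MTG", "TPOmid", "ITG"
)

# The 14 default-mode-network parcels used for edge-wise comparison.
dmn_labels <- c(
  "SFGdor.L", "SFGdor.R", "SFGmed.L", "SFGmed.R", "ACG.L", "ACG.R",
  "PCG.L", "PCG.R", "PHG.L", "PHG.R", "ANG.L", "ANG.R", "MTG.R", "ITG.L"
)

#' Construct a region atlas
#'
#' An atlas is a data frame with one row per region and columns `label`,
#' `hemisphere` (`"L"`/`"R"`), `dmn` (logical) and `volume` (positive).
#' Row order defines node order for every matrix in the package.
#'
#' @param label character vector of unique region codes.
#' @param hemisphere `"L"` or `"R"` per region.
#' @param dmn logical flag marking default-mode-network membership.
#' @param volume positive region volume (mm^3 or voxels).
#' @return a `region_atlas` data frame.
#' @export
region_atlas <- function(label, hemisphere, dmn, volume) {
  atlas <- data.frame(
    label = as.character(label),
    hemisphere = as.character(hemisphere),
    dmn = as.logical(dmn),
    volume = as.numeric(volume),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("region_atlas", "data.frame")
  validate_atlas(atlas)
}

#' @rdname region_atlas
#' @param atlas object to validate.
#' @export
validate_atlas <- function(atlas) {
  if (anyDuplicated(atlas$label)) stop_teanet("atlas labels must be unique")
  if (!all(atlas$hemisphere %in% c("L", "R"))) {
    stop_teanet("atlas hemisphere must be 'L' or 'R'")
  }
  if (any(!is.finite(atlas$volume)) || any(atlas$volume <= 0)) {
    stop_teanet("atlas volumes must be positive")
  }
  if (any(is.na(atlas$dmn))) stop_teanet("atlas dmn flags must be TRUE/FALSE")
  atlas
}

#' The 90-region AAL cerebral atlas
#'
#' Ninety cerebral parcels of the Automated Anatomical Labeling template,
#' alternating left/right hemisphere, with the 14 default-mode-network
#' parcels flagged. Volumes are SYNTHETIC: mirror-symmetric deterministic
#' values on a realistic scale (thousands of mm^3), not measured AAL parcel
#' volumes — suitable for simulation and testing, not for real cohorts
#' (supply measured volumes via [read_atlas()] for those).
#'
#' @return a `region_atlas` with 90 rows.
#' @export
aal90_atlas <- function() {
  base <- aal90_base_labels
  labels <- as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
  hemisphere <- rep(c("L", "R"), 45)
  # synthetic volumes: deterministic, heterogeneous, identical for the two
  # homologues of a parcel so volume normalization is mirror-symmetric
  vol_base <- 4000 + 500 * ((seq_len(45) * 17) %% 29)
  volume <- rep(vol_base, each = 2)
  region_atlas(labels, hemisphere, labels %in% dmn_labels, volume)
}

#' Read / write an atlas CSV
#'
#' Columns: `label`, `hemisphere`, `dmn`, `volume`.
#'
#' @param path file path.
#' @return `read_atlas`: a `region_atlas`; `write_atlas`: `path`, invisibly.
#' @export
read_atlas <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "hemisphere", "dmn", "volume")
  if (!all(need %in% names(df))) {
    stop_teanet("atlas file must have columns: ", paste(need, collapse = ", "))
  }
  region_atlas(df$label, df$hemisphere, df$dmn, df$volume)
}

#' @rdname read_atlas
#' @param atlas a `region_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  write.csv(as.data.frame(atlas), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# generic even-sized atlas for reduced-scale simulations; first 14 regions
# (7 homologous pairs) are flagged DMN when the atlas is large enough
toy_atlas <- function(n_regions) {
  if (n_regions %% 2L != 0L) stop_teanet("n_regions must be even")
  pair <- ceiling(seq_len(n_regions) / 2)
  side <- rep(c("L", "R"), n_regions / 2)
  labels <- sprintf("ROI%02d.%s", pair, side)
  dmn <- if (n_regions >= 14) seq_len(n_regions) <= 14 else rep(FALSE, n_regions)
  vol <- rep(4000 + 500 * ((seq_len(n_regions / 2) * 17) %% 29), each = 2)
  region_atlas(labels, side, dmn, vol)
}
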