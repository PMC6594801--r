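# Synthetic cohort generator: complete cohorts (ROI time series, streamline
# counts, volumes, demographics, tea-frequency records) with known planted
# group effects, so every pipeline stage can be checked against ground
# truth.
#
# Planted mechanisms:
#  * dmn_effect     — the population Pearson correlation of every DMN-DMN
#                     region pair is raised by this amount in the tea group
#  * sc_global_effect — expected streamline counts in the tea group are
#                     scaled by (1 + effect), a global structural advantage
#  * asym_effect    — leftward structural asymmetry planted in the NON-tea
#                     group by two mechanisms: all left-intra-hemispheric
#                     expected counts scaled by (1 + effect) (drives E_loc,
#                     E_glob, L_w leftward), and left association "hub"
#                     regions coupled into a strengthened clique (drives the
#                     clustering coefficient leftward, which a uniform
#                     scaling cannot do: Onnela clustering is invariant to
#                     it by construction). Each hemisphere also carries one
#                     strong fixed "anchor" connection so the maximum weight
#                     that normalizes the clustering coefficient is stable
#                     across subjects.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study cohort: 15 tea vs 21 non-tea subjects, 90
#' regions, 200 retained fMRI volumes, and the demographic distributions of
#' the screening table. Effect defaults are the smallest sizes the
#' acceptance properties are stated at (DMN correlation +0.25, structural
#' +10%); `asym_effect` defaults to +30% on left-hemisphere expected counts.
#'
#' @param n_tea,n_nontea group sizes (defaults 15, 21).
#' @param n_regions number of regions, even (default 90 = AAL cerebrum).
#' @param n_timepoints fMRI volumes per subject (default 200).
#' @param base_correlation baseline off-diagonal population correlation of
#'   the time series (default 0.1).
#' @param dmn_effect added population correlation on DMN-DMN pairs in the
#'   tea group (default 0.25).
#' @param sc_global_effect multiplicative structural advantage of the tea
#'   group (default 0.10).
#' @param asym_effect multiplicative left-left structural advantage of the
#'   non-tea group (default 0.30), planting leftward asymmetry there.
#' @param noise_sd marginal standard deviation of the simulated BOLD series
#'   (arbitrary units; amplitude only, correlations are set by the
#'   population correlation matrix). Default 1.
#' @param sc_scale expected streamline count of the strongest
#'   distance-decay template connection (default 60).
#' @param sc_decay exponential decay length of expected counts with
#'   inter-region distance, in homologous-pair index units (default 8).
#' @param sc_anchor each hemisphere carries one fixed strong connection of
#'   `sc_anchor * sc_scale` expected streamlines (default 6), pinning the
#'   maximum weight that normalizes the clustering coefficient.
#' @param sc_n_hubs number of left "hub" regions strengthened into a clique
#'   by the asymmetry effect (default 10).
#' @param sc_hub_gain expected-count addition on each hub pair is
#'   `asym_effect * sc_hub_gain * sc_scale` (default 3).
#' @param seed master seed; every stage derives its own substream.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_tea = 15, n_nontea = 21, n_regions = 90,
                          n_timepoints = 200, base_correlation = 0.1,
                          dmn_effect = 0.25, sc_global_effect = 0.10,
                          asym_effect = 0.30, noise_sd = 1,
                          sc_scale = 60, sc_decay = 8, sc_anchor = 6,
                          sc_n_hubs = 10, sc_hub_gain = 3, seed = 1) {
  cfg <- list(n_tea = n_tea, n_nontea = n_nontea, n_regions = n_regions,
              n_timepoints = n_timepoints, base_correlation = base_correlation,
              dmn_effect = dmn_effect, sc_global_effect = sc_global_effect,
              asym_effect = asym_effect, noise_sd = noise_sd,
              sc_scale = sc_scale, sc_decay = sc_decay, sc_anchor = sc_anchor,
              sc_n_hubs = sc_n_hubs, sc_hub_gain = sc_hub_gain, seed = seed)
  if (cfg$n_tea < 2 || cfg$n_nontea < 2) stop_teanet("group sizes must be >= 2")
  if (cfg$n_regions %% 2 != 0) stop_teanet("n_regions must be even")
  if (cfg$noise_sd <= 0) stop_teanet("noise_sd must be > 0")
  if (!all(is.finite(c(cfg$dmn_effect, cfg$sc_global_effect, cfg$asym_effect)))) {
    stop_teanet("effects must be finite")
  }
  if (cfg$dmn_effect < 0) stop_teanet("dmn_effect must be >= 0")
  class(cfg) <- "cohort_config"
  cfg
}

# population correlation matrix: compound symmetry at `base`, plus `effect`
# added to every DMN-DMN off-diagonal pair; positive definiteness checked
population_correlation <- function(n, base, dmn_idx, effect) {
  R <- matrix(base, n, n)
  diag(R) <- 1
  if (effect > 0 && length(dmn_idx) >= 2) {
    R[dmn_idx, dmn_idx] <- R[dmn_idx, dmn_idx] + effect
    diag(R) <- 1
  }
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    stop_teanet("implied correlation matrix is not positive definite; ",
                "use smaller effects (base_correlation + dmn_effect too large)")
  }
  list(R = R, chol = ch)
}

# expected streamline counts: exponential distance decay on homologous-pair
# index distance, damped for inter-hemispheric pairs; mirror-symmetric.
# One fixed strong "anchor" connection per hemisphere (between the first
# two homologous-pair positions) pins the network maximum.
sc_template <- function(atlas, scale, decay, anchor = 0) {
  n <- nrow(atlas)
  pos <- ceiling(seq_len(n) / 2)
  same_h <- outer(atlas$hemisphere, atlas$hemisphere, `==`)
  mu <- scale * exp(-abs(outer(pos, pos, `-`)) / decay)
  mu[!same_h] <- mu[!same_h] * 0.3
  if (anchor > 0 && max(pos) >= 2) {
    for (h in c("L", "R")) {
      i <- which(atlas$hemisphere == h & pos == 1)
      j <- which(atlas$hemisphere == h & pos == 2)
      mu[i, j] <- mu[j, i] <- anchor * scale
    }
  }
  diag(mu) <- 0
  mu
}

# left "hub" region indices: evenly spaced homologous-pair positions
left_hub_idx <- function(atlas, n_hubs) {
  n <- nrow(atlas)
  pos <- ceiling(seq_len(n) / 2)
  npos <- max(pos)
  if (npos < 3 || n_hubs < 2) return(integer(0))
  hub_pos <- unique(round(seq(3, npos - 1, length.out = min(n_hubs, npos - 3))))
  which(atlas$hemisphere == "L" & pos %in% hub_pos)
}

# symmetric Poisson draw around a mean matrix
rpois_symmetric <- function(mu) {
  n <- nrow(mu)
  up <- upper.tri(mu)
  out <- matrix(0L, n, n, dimnames = dimnames(mu))
  out[up] <- stats::rpois(sum(up), mu[up])
  out + t(out)
}

#' Generate a synthetic cohort with planted effects
#'
#' Produces, from a single seed: per-subject ROI time series (zero-mean
#' multivariate normal with the group's population correlation matrix),
#' symmetric streamline-count matrices (Poisson around a mirror-symmetric
#' distance-decay template with the group's planted scalings), an atlas, a
#' cohort table (demographics, tea-frequency records, neuropsychological
#' scores), and the ground truth of what was planted.
#'
#' @param config a [cohort_config()].
#' @return list: `timeseries` (named list of timepoint x region matrices),
#'   `streamlines` (named list of count matrices), `atlas`, `cohort`
#'   (data frame), `ground_truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  atlas <- if (cfg$n_regions == 90) aal90_atlas() else toy_atlas(cfg$n_regions)
  n_sub <- cfg$n_tea + cfg$n_nontea
  ids <- sprintf("sub%03d", seq_len(n_sub))
  groups <- c(rep("T", cfg$n_tea), rep("NT", cfg$n_nontea))
  dmn_idx <- which(atlas$dmn)

  pop_nt <- population_correlation(cfg$n_regions, cfg$base_correlation,
                                   dmn_idx, 0)
  pop_t <- population_correlation(cfg$n_regions, cfg$base_correlation,
                                  dmn_idx, cfg$dmn_effect)

  # --- functional time series -------------------------------------------
  ts <- with_seed(derive_seed(cfg$seed, "timeseries"), {
    lapply(seq_len(n_sub), function(s) {
      ch <- if (groups[s] == "T") pop_t$chol else pop_nt$chol
      z <- matrix(stats::rnorm(cfg$n_timepoints * cfg$n_regions),
                  cfg$n_timepoints, cfg$n_regions)
      x <- cfg$noise_sd * (z %*% ch)
      colnames(x) <- atlas$label
      x
    })
  })
  names(ts) <- ids

  # --- structural streamline counts -------------------------------------
  mu0 <- sc_template(atlas, cfg$sc_scale, cfg$sc_decay, cfg$sc_anchor)
  left <- atlas$hemisphere == "L"
  ll <- outer(left, left, `&`)
  hubs <- left_hub_idx(atlas, cfg$sc_n_hubs)
  sc <- with_seed(derive_seed(cfg$seed, "streamlines"), {
    lapply(seq_len(n_sub), function(s) {
      mu <- mu0
      if (groups[s] == "T") mu <- mu * (1 + cfg$sc_global_effect)
      if (groups[s] == "NT" && cfg$asym_effect > 0) {
        mu[ll] <- mu[ll] * (1 + cfg$asym_effect)
        if (length(hubs) >= 2) {
          mu[hubs, hubs] <- mu[hubs, hubs] +
            cfg$asym_effect * cfg$sc_hub_gain * cfg$sc_scale
          diag(mu) <- 0
        }
      }
      rpois_symmetric(mu)
    })
  })
  names(sc) <- ids

  # --- demographics, tea records, neuropsychological scores --------------
  cohort <- with_seed(derive_seed(cfg$seed, "demographics"), {
    age <- ifelse(groups == "T",
                  stats::rnorm(n_sub, 70.27, 5.52),
                  stats::rnorm(n_sub, 71.71, 3.98))
    age <- pmin(pmax(age, 60), 90)
    edu <- ifelse(groups == "T",
                  stats::rnorm(n_sub, 6.00, 3.96),
                  stats::rnorm(n_sub, 4.81, 3.50))
    edu <- round(pmin(pmax(edu, 0), 16))
    sex <- ifelse(stats::runif(n_sub) < ifelse(groups == "T", 4 / 15, 2 / 21),
                  "male", "female")
    hand <- ifelse(stats::runif(n_sub) < ifelse(groups == "T", 0, 1 / 21),
                   "left", "right")
    # tea records consistent with the group: NT never drinks tea (score 3);
    # T drinks two favourite teas 4+ times a week at both ages, which
    # guarantees a composite score of at least 9
    rec <- data.frame(green_45 = rep(1L, n_sub), oolong_45 = 1L, black_45 = 1L,
                      green_now = 1L, oolong_now = 1L, black_now = 1L,
                      coffee_45 = sample(1:6, n_sub, replace = TRUE),
                      coffee_now = sample(1:6, n_sub, replace = TRUE))
    for (s in which(groups == "T")) {
      fav <- sample(c("green", "oolong", "black"), 2)
      for (f in fav) {
        rec[[paste0(f, "_45")]][s] <- sample(4:6, 1)
        rec[[paste0(f, "_now")]][s] <- sample(4:6, 1)
      }
    }
    scores <- matrix(stats::rnorm(n_sub * 12, 50, 10), n_sub, 12)
    colnames(scores) <- c("RAVLT_ir", "RAVLT_dr", "DigitSpan_fwd",
                          "DigitSpan_bwd", "SDMT_written", "SDMT_oral",
                          "BostonNaming", "BlockDesign", "CTT1", "CTT2",
                          "MMSE", "MoCA")
    cbind(data.frame(subject_id = ids, age = age, education = edu,
                     sex = sex, handedness = hand,
                     stringsAsFactors = FALSE),
          rec, as.data.frame(scores))
  })
  cohort <- screen_cohort(cohort)
  if (!identical(cohort$group, groups)) {
    stop_teanet("internal error: screened groups disagree with planted groups")
  }

  dmn_pairs <- if (length(dmn_idx) >= 2) {
    p <- utils::combn(dmn_idx, 2)
    paste(atlas$label[p[1, ]], atlas$label[p[2, ]], sep = "--")
  } else character(0)

  list(
    timeseries = ts,
    streamlines = sc,
    atlas = atlas,
    cohort = cohort,
    ground_truth = list(
      groups = stats::setNames(groups, ids),
      dmn_effect = cfg$dmn_effect,
      dmn_pairs = dmn_pairs,
      sc_global_effect = cfg$sc_global_effect,
      asym_effect = cfg$asym_effect,
      asym_group = "NT",
      asym_hub_regions = atlas$label[hubs]
    ),
    config = cfg
  )
}

#' Generate a null cohort (all planted effects zero)
#'
#' Same construction as [generate_cohort()] with every group effect forced
#' to zero, so the two groups are exchangeable; used by calibration tests.
#'
#' @param config a [cohort_config()]; its effect fields are overridden.
#' @return see [generate_cohort()].
#' @export
generate_null_cohort <- function(config = cohort_config()) {
  config$dmn_effect <- 0
  config$sc_global_effect <- 0
  config$asym_effect <- 0
  generate_cohort(config)
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the pipeline consumes: `atlas.csv`,
#' `cohort.csv`, `timeseries/<id>.tsv`, `streamlines/<id>.tsv`, and a
#' `manifest.txt` (key/value header plus a JSON block with the full config
#' and ground truth).
#'
#' @param cohort_data output of [generate_cohort()].
#' @param dir target directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort_data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  dir.create(file.path(dir, "streamlines"), showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "atlas.csv"); write_atlas(cohort_data$atlas, p)
  paths <- c(paths, p)
  p <- file.path(dir, "cohort.csv")
  write.csv(cohort_data$cohort, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  for (id in names(cohort_data$timeseries)) {
    p <- file.path(dir, "timeseries", paste0(id, ".tsv"))
    utils::write.table(cohort_data$timeseries[[id]], p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  for (id in names(cohort_data$streamlines)) {
    m <- cohort_data$streamlines[[id]]
    dimnames(m) <- list(cohort_data$atlas$label, cohort_data$atlas$label)
    p <- file.path(dir, "streamlines", paste0(id, ".tsv"))
    write_matrix_tsv(m, p)
    paths <- c(paths, p)
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c(
    paste0("generator: teanet ", as.character(utils::packageVersion("teanet"))),
    paste0("seed: ", cohort_data$config$seed),
    paste0("n_subjects: ", length(cohort_data$timeseries)),
    "config_json:",
    jsonlite::toJSON(unclass(cohort_data$config), auto_unbox = TRUE),
    "ground_truth_json:",
    jsonlite::toJSON(cohort_data$ground_truth, auto_unbox = TRUE)
  ), manifest)
  paths <- c(paths, manifest)
  invisible(paths)
}
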