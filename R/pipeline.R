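# End-to-end orchestration: read a cohort from disk, run screening,
# network construction, metric sweeps, asymmetry, and all group
# comparisons; write the report bundle atomically.

#' Run configuration
#'
#' @param cohort_csv path to the cohort table CSV.
#' @param timeseries_dir directory of per-subject time-series TSVs
#'   (`<subject_id>.tsv`).
#' @param streamlines_dir directory of per-subject streamline-count TSVs.
#' @param atlas_csv path to the atlas CSV.
#' @param out_dir output directory for the report bundle.
#' @param s_min,s_max,step sparsity sweep grid (defaults 0.1, 0.4, 0.01).
#' @param negative_policy handling of negative correlations (`"zero"` or
#'   `"absolute"`).
#' @param threshold_structural logical; sweep structural networks too
#'   (default `FALSE`: structural networks are naturally sparse and are
#'   analyzed unthresholded).
#' @param n_perm permutations per test (default 10000).
#' @param seed master seed for all permutation streams.
#' @param alpha significance level for exploratory flags (default 0.05).
#' @param clustering_method `"onnela"` or `"barrat"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_csv, timeseries_dir, streamlines_dir, atlas_csv,
                       out_dir, s_min = 0.1, s_max = 0.4, step = 0.01,
                       negative_policy = "zero", threshold_structural = FALSE,
                       n_perm = 10000, seed = 1, alpha = 0.05,
                       clustering_method = "onnela") {
  cfg <- list(cohort_csv = cohort_csv, timeseries_dir = timeseries_dir,
              streamlines_dir = streamlines_dir, atlas_csv = atlas_csv,
              out_dir = out_dir, s_min = s_min, s_max = s_max, step = step,
              negative_policy = negative_policy,
              threshold_structural = threshold_structural,
              n_perm = n_perm, seed = seed, alpha = alpha,
              clustering_method = clustering_method)
  class(cfg) <- "run_config"
  cfg
}

#' Validate pipeline inputs without running the analysis
#'
#' Checks that every referenced file exists, dimensions agree with the
#' atlas, streamline matrices are symmetric, and tea-frequency scales are
#' in range. Non-destructive: returns a report instead of stopping.
#'
#' @param config a [run_config()].
#' @return character vector of problems (empty when everything is valid).
#' @export
validate_inputs <- function(config) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  for (p in c(config$cohort_csv, config$atlas_csv)) {
    if (!file.exists(p)) note("missing file: ", p)
  }
  for (p in c(config$timeseries_dir, config$streamlines_dir)) {
    if (!dir.exists(p)) note("missing directory: ", p)
  }
  if (length(problems)) return(problems)
  atlas <- tryCatch(read_atlas(config$atlas_csv),
                    error = function(e) { note(conditionMessage(e)); NULL })
  cohort <- tryCatch(read.csv(config$cohort_csv, stringsAsFactors = FALSE),
                     error = function(e) { note(conditionMessage(e)); NULL })
  if (is.null(atlas) || is.null(cohort)) return(problems)
  for (f in intersect(tea_scale_fields, names(cohort))) {
    bad <- which(!(cohort[[f]] %in% 1:6))
    if (length(bad)) note("out-of-range scale ", f, " for subject row(s) ",
                          paste(bad, collapse = ","))
  }
  for (id in cohort$subject_id) {
    tsp <- file.path(config$timeseries_dir, paste0(id, ".tsv"))
    scp <- file.path(config$streamlines_dir, paste0(id, ".tsv"))
    if (!file.exists(tsp)) { note("missing time series for subject ", id); next }
    if (!file.exists(scp)) { note("missing streamlines for subject ", id); next }
    ts <- tryCatch(read_timeseries(tsp), error = function(e) NULL)
    if (is.null(ts) || ncol(ts) != nrow(atlas)) {
      note("time-series column count != atlas size for subject ", id)
    }
    m <- tryCatch(read_matrix_tsv(scp), error = function(e) NULL)
    if (is.null(m) || nrow(m) != nrow(atlas)) {
      note("streamline matrix dimension != atlas size for subject ", id)
    } else if (max(abs(m - t(m))) > 0) {
      ij <- which(m != t(m), arr.ind = TRUE)[1, ]
      note("asymmetric streamline matrix for subject ", id,
           " at entry (", ij[1], ",", ij[2], ")")
    }
  }
  problems
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: screening and demographics; per-subject functional and
#' structural network construction; metric sweeps (functional swept over
#' sparsity, structural unthresholded unless configured otherwise);
#' hemispheric asymmetry; group comparisons of neuropsychological scores,
#' global metrics, nodal efficiencies, asymmetry indices, and DMN edges.
#' Reports are staged in a temporary directory and moved into place only on
#' success, so a failed run leaves no partial bundle. Re-running with the
#' same config and seed reproduces identical numbers.
#'
#' @param config a [run_config()].
#' @return invisible list of result data frames (also written as TSVs).
#' @export
run_pipeline <- function(config) {
  problems <- validate_inputs(config)
  if (length(problems)) {
    stop_teanet("invalid inputs:\n  ", paste(problems, collapse = "\n  "))
  }
  atlas <- read_atlas(config$atlas_csv)
  cohort <- read.csv(config$cohort_csv, stringsAsFactors = FALSE)
  cohort <- screen_cohort(cohort)
  keep <- cohort$group %in% c("T", "NT")
  cohort <- cohort[keep, , drop = FALSE]
  if (sum(cohort$group == "T") < 2 || sum(cohort$group == "NT") < 2) {
    stop_teanet("fewer than 2 subjects per group after screening")
  }
  groups <- cohort$group
  ids <- cohort$subject_id

  stage <- file.path(dirname(config$out_dir),
                     paste0(".", basename(config$out_dir), ".staging"))
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  results <- list()

  # --- screening / demographics -----------------------------------------
  results$demographics <- demographic_table(cohort)
  measures <- intersect(c("RAVLT_ir", "RAVLT_dr", "DigitSpan_fwd",
                          "DigitSpan_bwd", "SDMT_written", "SDMT_oral",
                          "BostonNaming", "BlockDesign", "CTT1", "CTT2",
                          "MMSE", "MoCA"), names(cohort))
  if (length(measures) >= 2) {
    results$neuropsych <- compare_neuropsych(
      cohort, measures, config$n_perm, derive_seed(config$seed, "neuropsych"))
  }

  # --- networks and metrics ---------------------------------------------
  fc <- sc <- vector("list", length(ids)); names(fc) <- names(sc) <- ids
  glob <- nodal <- asym <- list(functional = list(), structural = list())
  asym_tidy <- list()
  for (id in ids) {
    ts <- read_timeseries(file.path(config$timeseries_dir, paste0(id, ".tsv")),
                          atlas)
    fc[[id]] <- build_functional_network(ts, config$negative_policy, id)
    counts <- read_matrix_tsv(file.path(config$streamlines_dir,
                                        paste0(id, ".tsv")))
    sc[[id]] <- build_structural_network(counts[atlas$label, atlas$label],
                                         atlas, id)
    sw <- sweep_and_integrate(fc[[id]], config$s_min, config$s_max,
                              config$step, config$clustering_method)
    glob$functional[[id]] <- unlist(sw$integrated[c("C_w", "L_w", "E_loc", "E_glob")])
    nodal$functional[[id]] <- sw$integrated$nodal
    if (config$threshold_structural) {
      sws <- sweep_and_integrate(sc[[id]], config$s_min, config$s_max,
                                 config$step, config$clustering_method)
      glob$structural[[id]] <- unlist(sws$integrated[c("C_w", "L_w", "E_loc", "E_glob")])
      nodal$structural[[id]] <- sws$integrated$nodal
    } else {
      g <- global_metrics(sc[[id]], config$clustering_method)
      glob$structural[[id]] <- unlist(g[c("C_w", "L_w", "E_loc", "E_glob")])
      nodal$structural[[id]] <- g$nodal
    }
    for (mod in c("functional", "structural")) {
      net <- if (mod == "functional") fc[[id]] else sc[[id]]
      ha <- hemisphere_asymmetry(net, atlas,
                                 sweep = mod == "functional" || config$threshold_structural,
                                 config$s_min, config$s_max, config$step,
                                 config$clustering_method)
      asym[[mod]][[id]] <- stats::setNames(ha$index, ha$metric)
      asym_tidy[[paste(id, mod)]] <- cbind(subject_id = id, modality = mod, ha)
    }
  }
  results$subject_asymmetry <- do.call(rbind, asym_tidy)
  rownames(results$subject_asymmetry) <- NULL

  # --- group comparisons -------------------------------------------------
  comp_global <- comp_nodal <- comp_asym <- comp_dmn <- list()
  for (mod in c("functional", "structural")) {
    gm <- do.call(rbind, glob[[mod]])
    comp_global[[mod]] <- cbind(modality = mod,
      compare_global_metrics(gm, groups, config$n_perm,
                             derive_seed(config$seed, paste0("global_", mod))))
    nm <- do.call(rbind, nodal[[mod]])
    comp_nodal[[mod]] <- cbind(modality = mod,
      compare_nodal_efficiency(nm, groups, config$n_perm,
                               derive_seed(config$seed, paste0("nodal_", mod))))
    am <- do.call(rbind, asym[[mod]])
    comp_asym[[mod]] <- cbind(modality = mod,
      compare_asymmetry(am, groups, config$n_perm,
                        derive_seed(config$seed, paste0("asym_", mod))))
    nets <- if (mod == "functional") fc else sc
    if (any(atlas$dmn)) {
      comp_dmn[[mod]] <- cbind(modality = mod,
        compare_dmn_edges(nets, groups, atlas, config$n_perm,
                          derive_seed(config$seed, paste0("dmn_", mod)),
                          alpha = config$alpha))
    }
  }
  results$global_metrics <- do.call(rbind, unname(comp_global))
  results$nodal_efficiency <- do.call(rbind, unname(comp_nodal))
  results$asymmetry <- do.call(rbind, unname(comp_asym))
  if (length(comp_dmn)) results$dmn_edges <- do.call(rbind, unname(comp_dmn))

  # per-subject metric values, tidy
  tidy <- do.call(rbind, lapply(c("functional", "structural"), function(mod) {
    do.call(rbind, lapply(ids, function(id) {
      v <- glob[[mod]][[id]]
      data.frame(subject_id = id, modality = mod, metric = names(v),
                 value = unname(v), row.names = NULL)
    }))
  }))
  results$subject_metrics <- tidy

  for (nm in names(results)) {
    write_tsv(results[[nm]], file.path(stage, paste0(nm, ".tsv")))
  }
  # machine-readable summary of every comparison family
  jsonlite::write_json(
    results[intersect(c("demographics", "neuropsych", "global_metrics",
                        "nodal_efficiency", "asymmetry", "dmn_edges"),
                      names(results))],
    file.path(stage, "summary.json"), dataframe = "rows", digits = NA)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  writeLines(c(
    paste0("teanet version: ", as.character(utils::packageVersion("teanet"))),
    paste0("seed: ", config$seed),
    paste0("config_sha: ", substr(paste(as.integer(charToRaw(cfg_json)),
                                        collapse = ""), 1, 40)),
    "config_json:", cfg_json
  ), file.path(stage, "run_log.txt"))

  unlink(config$out_dir, recursive = TRUE)
  if (!file.rename(stage, config$out_dir)) {
    stop_teanet("could not move staged results into ", config$out_dir)
  }
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `validate`, and
#' `run-all` (full pipeline). Invoke from Rscript as
#' `Rscript -e 'teanet::teanet_cli()' simulate --out dir --seed 1`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit status, invisibly.
#' @export
teanet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: teanet <simulate|validate|run-all> [--key value ...]",
    "  simulate --out DIR [--seed N] [--n-tea N] [--n-nontea N] [--n-regions N] [--n-timepoints N]",
    "  validate --cohort CSV --timeseries DIR --streamlines DIR --atlas CSV",
    "  run-all  --cohort CSV --timeseries DIR --streamlines DIR --atlas CSV --out DIR",
    "           [--n-perm N] [--seed N] [--alpha A] [--threshold-structural]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(); flagless <- character(0)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (key == "threshold-structural") { opts[[key]] <- TRUE; i <- i + 1 }
    else { opts[[key]] <- args[i + 1]; i <- i + 2 }
  }
  num <- function(k, d) if (is.null(opts[[k]])) d else as.numeric(opts[[k]])
  chr <- function(k) opts[[k]]
  if (cmd == "simulate") {
    cfg <- cohort_config(n_tea = num("n-tea", 15), n_nontea = num("n-nontea", 21),
                         n_regions = num("n-regions", 90),
                         n_timepoints = num("n-timepoints", 200),
                         seed = num("seed", 1))
    write_cohort(generate_cohort(cfg), chr("out"))
    message("cohort written to ", chr("out"))
    return(invisible(0L))
  }
  cfg <- run_config(chr("cohort"), chr("timeseries"), chr("streamlines"),
                    chr("atlas"), out_dir = chr("out"),
                    n_perm = num("n-perm", 10000), seed = num("seed", 1),
                    alpha = num("alpha", 0.05),
                    threshold_structural = isTRUE(opts[["threshold-structural"]]))
  if (cmd == "validate") {
    problems <- validate_inputs(cfg)
    if (length(problems)) { message(paste(problems, collapse = "\n")); return(invisible(1L)) }
    message("inputs valid"); return(invisible(0L))
  }
  if (cmd == "run-all") {
    run_pipeline(cfg)
    message("report bundle written to ", cfg$out_dir)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
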