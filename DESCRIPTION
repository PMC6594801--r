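Package: teanet
Title: Group Analysis of Functional and Structural Brain Connectivity Networks
Version: 0.1.0
Authors@R:
    person("teanet", "maintainers", email = "maintainers@teanet.dev", role = c("aut", "cre"))
Description: Constructs ROI-level functional (Pearson correlation) and
    structural (volume-normalized streamline count) connectivity networks,
    computes weighted graph-theoretic metrics (clustering coefficient,
    characteristic path length, local and global efficiency, nodal
    efficiency) over a proportional sparsity-threshold sweep with trapezoid
    integration, quantifies hemispheric asymmetry of network metrics via a
    laterality index on intra-hemispheric sub-networks, compares default
    mode network edge strengths, and performs permutation-based group
    inference with Benjamini-Hochberg FDR control. Ships a synthetic-cohort
    generator with planted group effects so every stage of the pipeline can
    be validated against known ground truth, plus cohort screening utilities
    based on a tea-drinking frequency composite score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
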