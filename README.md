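# teanet

Group analysis of functional and structural brain connectivity networks,
built around a tea-drinking vs non-tea-drinking cohort design in older
adults.

## The scientific problem

Habitual tea drinking has been linked to slower age-related cognitive
decline, but most evidence is neuropsychological. The system-level
question is whether tea drinkers' brains are *organized* differently: more
efficient interregional wiring, less of the leftward hemispheric asymmetry
that accompanies ageing, stronger default mode network (DMN) coupling.
teanet implements the full analysis needed to ask that question from
ROI-level imaging products:

1. **Screening** — a tea-frequency composite score (three teas, two
   recall ages, 1–6 ordinal scales; coffee recorded but excluded) assigns
   subjects to tea (score ≥ 8), non-tea (score = 3) or excluded groups,
   and classical statistics (pooled t, uncorrected Pearson χ²) compare
   demographics.
2. **Networks** — functional connectivity as the Pearson correlation of
   regional fMRI time series (negatives zeroed by default); structural
   connectivity as streamline counts normalized by the sum of the two
   region volumes; 90-region AAL node set.
3. **Graph metrics** — weighted clustering coefficient C_w (Onnela),
   characteristic path length L_w, local and global efficiency
   E_loc/E_glob, and per-region nodal efficiency, with edge length 1/w.
   Functional networks are proportionally thresholded over a sparsity
   sweep (0.10–0.40, step 0.01) and each metric integrated over the sweep
   (trapezoid rule).
4. **Hemispheric asymmetry** — each metric X computed on the two 45-region
   intra-hemispheric subnetworks and combined as
   (X_L − X_R)/(X_L + X_R); positive = leftward.
5. **Inference** — label-permutation tests (difference of group means,
   two-sided, exact enumeration when feasible) with Benjamini–Hochberg
   FDR within each corrected family; nodal and DMN-edge comparisons are
   reported uncorrected and flagged exploratory.
6. **Synthetic cohorts** — a generator plants known effects (DMN
   correlation +0.25 in the tea group, +10% structural streamline
   expectations, leftward structural asymmetry in the non-tea group) so
   every stage is testable against ground truth.

## Worked example

```r
library(teanet)

# a synthetic cohort at the study's dimensions, planting only the
# structural advantage (+10% streamline expectations in the tea group)
ch <- generate_cohort(cohort_config(dmn_effect = 0, asym_effect = 0,
                                    seed = 42))
table(ch$cohort$group)
#> NT  T
#> 21 15

# structural networks and global metrics for every subject
atlas <- ch$atlas
gm <- t(sapply(names(ch$streamlines), function(id) {
  net <- build_structural_network(ch$streamlines[[id]], atlas, id)
  unlist(global_metrics(net)[c("C_w", "L_w", "E_loc", "E_glob")])
}))

res <- compare_global_metrics(gm, ch$cohort$group, n_perm = 1000, seed = 42)
res[, c("variable", "observed_diff", "p", "q")]
#>   variable observed_diff        p        q
#> 1      C_w    -7.671e-05 0.790210 0.790210
#> 2      L_w    -1.412e+02 0.000999 0.001332
#> 3    E_loc     9.570e-05 0.000999 0.001332
#> 4   E_glob     9.580e-05 0.000999 0.001332
```

The planted +10% structural advantage of the tea group surfaces exactly
where it should: shorter characteristic path length (negative difference,
T − NT) and higher local/global efficiency, significant after FDR — while
C_w, whose Onnela normalization cancels uniform weight scalings, stays
null. The same machinery drives the screening report
(`demographic_table`), asymmetry comparison (`hemisphere_asymmetry` +
`compare_asymmetry`), and DMN edge screen (`compare_dmn_edges`).

The full pipeline runs from files on disk:

```r
write_cohort(ch, "cohort_dir")
cfg <- run_config("cohort_dir/cohort.csv", "cohort_dir/timeseries",
                  "cohort_dir/streamlines", "cohort_dir/atlas.csv",
                  out_dir = "report", n_perm = 1000, seed = 42)
run_pipeline(cfg)   # writes report/*.tsv + run_log.txt atomically
```

or from the command line:

```sh
Rscript -e 'teanet::teanet_cli()' simulate --out cohort_dir --seed 42
Rscript -e 'teanet::teanet_cli()' run-all --cohort cohort_dir/cohort.csv \
  --timeseries cohort_dir/timeseries --streamlines cohort_dir/streamlines \
  --atlas cohort_dir/atlas.csv --out report
```

## Notes

- The shipped `aal90_atlas()` carries *synthetic* mirror-symmetric region
  volumes for simulation; supply measured volumes via `read_atlas()` for
  real data.
- See `vignettes/methods.Rmd` for the model conventions (weight→length
  map, clustering formulation, disconnection handling, FDR families) and
  for what the synthetic generator does and does not emulate.
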