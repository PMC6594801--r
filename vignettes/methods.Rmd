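---
title: "Models and methods behind teanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind teanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teanet)
```

## What the package computes

teanet is a group-comparison pipeline for ROI-level brain connectivity.
Given per-subject regional fMRI time series and streamline-count matrices
on a common 90-region cerebral atlas, it constructs one functional and one
structural weighted network per subject, characterizes each network with
weighted graph metrics, quantifies hemispheric asymmetry, compares default
mode network (DMN) edge strengths, and tests group differences between a
tea-drinking (T) and a non-tea-drinking (NT) cohort with label-permutation
tests under Benjamini–Hochberg false-discovery-rate control.

## Cohort screening

Tea-drinking frequency for green, oolong and black tea is recorded on a
six-level ordinal scale, recalled for age around 45 and for the present.
The composite score sums the three scales within each age and averages the
two sums, so it ranges over [3, 18]. A score of at least 8 assigns a
subject to group T; the minimum score of exactly 3 (never/rarely drank any
tea at either age) assigns NT; intermediate scores are excluded. Note the
strictness of this design: a subject drinking two kinds of tea weekly at
both ages scores 7 and is excluded, even though a verbal reading of
"two kinds of tea at least 1–3 times a week" suggests membership of T.
The formula is authoritative here; the package implements it literally and
labels the intermediate scores `excluded` rather than folding them into NT.
Coffee frequency is carried through the records and compared between
groups, but never enters the score.

Demographic comparisons use the classical statistics whose printed values
can be recomputed from summary data: the pooled-variance two-sample t
(df = n1 + n2 − 2; the printed df of 34 identifies pooling rather than the
Welch form) and the uncorrected Pearson chi-square for 2×2 tables (the
printed values 1.85 and 0.73 are only reproduced without the Yates
correction). Neuropsychological scores are compared with the same
permutation machinery as every other variable, corrected across the family
of 12 measures.

## Network construction

**Functional.** The edge weight between two regions is the Pearson
correlation of their ROI-averaged time series. Negative correlations are
zeroed by default; the weighted metrics used here assume nonnegative
weights, and zeroing is the least surprising of the available conventions.
An absolute-value policy is available as a configuration switch so the two
choices can be compared; the choice is recorded in the network's metadata.

**Structural.** The edge weight is the streamline count between two
regions divided by the *sum* of their two volumes. The normalization
denominator is genuinely ambiguous in the field ("normalized by the
volumes of the two ROIs" admits sum, mean, or product); the sum is adopted,
fixed, and recorded in output metadata so every result is self-describing.
Mean normalization would scale all weights by exactly 2 and leave every
scale-invariant conclusion unchanged.

**Proportional thresholding.** For sparsity s, the K = round(s·N(N−1)/2)
largest-weight edges are retained at their original weights and all others
set to zero (round half away from zero, so K is deterministic). Ties are
broken by ascending (row, column) edge index, which makes thresholding
reproducible and gives the nesting property the sweep relies on: the edge
set at a lower sparsity is always a subset of the edge set at a higher
one. The sweep is applied to functional networks, which are dense by
construction; structural networks are naturally sparse and analyzed
unthresholded by default, with a configuration flag to sweep them too.

## Graph metrics

All metrics operate on nonnegative weights. Edge length is the reciprocal
of edge weight (1/w); this is the dominant convention in the connectome
literature. All-pairs shortest paths come from Dijkstra's algorithm (the
test suite checks them against an independent Floyd–Warshall
implementation).

- **Global efficiency** E_glob: mean over ordered pairs of 1/d(i,j), with
  1/∞ = 0, so disconnection is handled natively.
- **Nodal efficiency**: the same mean restricted to one source region.
- **Characteristic path length** L_w: the mean of *finite* pairwise
  distances. Disconnected pairs are excluded from the mean and their count
  reported, rather than substituting an arbitrary finite penalty.
- **Weighted clustering coefficient** C_w: Onnela's form — weights
  normalized by the network maximum, per-node geometric mean of triangle
  weights over the k(k−1) ordered neighbour pairs, zero for degree < 2,
  averaged over nodes. Barrat's form is available behind a switch. The
  Onnela form is the default of the standard brain-connectivity toolboxes;
  note that it is invariant to a global rescaling of the weights, a
  property that matters for the synthetic generator below.
- **Local efficiency** E_loc: mean over nodes of the global efficiency of
  the subnetwork induced by each node's neighbours, with the original
  weights on that subset.

**Sweep integration.** Each global metric is computed at 31 sparsity
levels (0.10 to 0.40 in steps of 0.01) and integrated over sparsity by the
trapezoid rule, which is exact for linear level curves and stable on 31
points; a metric constant at c integrates to 0.3·c. The integrated value
is the quantity compared between groups.

## Hemispheric asymmetry

Inter-hemispheric connections are discarded and each hemisphere's 45×45
induced subnetwork analyzed separately. The asymmetry of metric X is
(X_L − X_R)/(X_L + X_R): +1 fully leftward, 0 symmetric. When the
denominator is zero the index is undefined and propagates as missing (the
subject is dropped from that metric's comparison with a warning), never
silently as 0. For functional networks the sparsity sweep is applied *per
sub-network* — K computed from the 45-node sub-network's own 990 possible
edges — before metric computation, keeping the two hemispheres at matched
density, which the index implicitly assumes; asymmetry is then computed
on integrated values. Whether thresholding preceded or followed the split
in the original analysis is not stated; matched density is the
interpretation under which the index is well-calibrated.

## Group inference

The test statistic is the difference of group means (T − NT), two-sided
via its absolute value; a pooled-t variant is available but the mean
difference is the default (the simplest exchangeable statistic consistent
with directional reporting). P-values come from permutations of group
labels: when the number of distinct label assignments is at most the
requested permutation count the test enumerates all of them and is exact;
otherwise assignments are sampled with replacement and
p = (1 + #{|Δ*| ≥ |Δ_obs|})/(1 + n_perm), so p can never be 0 and never
falls below 1/(n_perm+1). All variables of a family share one stream of
label permutations, and every stream derives from the run seed by stage
name, so reruns are bit-identical.

FDR families follow which analyses are reported corrected: the 12
neuropsychological measures; the 4 global metrics within a modality; the
4 asymmetry indices within a modality. Nodal efficiencies (90 tests) and
DMN edges (91 tests) are deliberately *uncorrected* and flagged
exploratory in the output, mirroring the hypothesis-generating role of
regional results.

## The synthetic cohort: a stated world

The generator emulates the study cohort — 15 vs 21 subjects, 90 regions,
200 retained fMRI volumes — with three planted mechanisms, each sized by
the smallest effect the acceptance properties are stated at:

- **DMN coupling** (`dmn_effect = 0.25`): the population correlation
  matrix is compound-symmetric at `base_correlation = 0.1` with the
  DMN–DMN block raised by +0.25 in group T. The block edit is applied
  directly to the correlation matrix and positive definiteness is checked
  by Cholesky factorization, with a clear error when effects are too
  large. A latent-factor construction was considered (it guarantees
  positive definiteness mechanically) but the direct edit makes the
  planted quantity *exactly* the stated correlation increment, which is
  what the recovery properties quantify; the Cholesky check covers the
  failure mode the latent construction avoids.
- **Structural advantage** (`sc_global_effect = 0.10`): expected
  streamline counts are Poisson around a mirror-symmetric distance-decay
  template (strongest connection ~60 streamlines, decay length 8
  homologous-pair positions, inter-hemispheric pairs damped to 30%);
  group T's expectations are scaled by 1.10, which propagates linearly to
  global efficiency under the 1/w length map.
- **Leftward asymmetry in NT** (`asym_effect = 0.30`): two coupled
  mechanisms. All left-intra-hemispheric expectations are scaled by 1.30,
  which drives E_loc, E_glob and L_w leftward but *cannot* move Onnela's
  C_w, since that statistic is invariant to uniform rescaling. C_w is made
  recoverable by additionally strengthening a clique of 10 evenly spaced
  left "hub" regions (adding `asym_effect × 3 × sc_scale` expected
  streamlines per hub pair), i.e. asymmetry concentrated in association
  hubs rather than spread uniformly — which is also the more plausible
  anatomy. Each hemisphere carries one strong fixed "anchor" connection
  (6× the template maximum) so the maximum weight that normalizes C_w is
  stable across subjects instead of jittering with Poisson noise.

The three mechanisms interact when planted jointly: the NT asymmetry
planting is itself a global structural group difference (it raises NT's
whole-brain efficiency), large enough to overturn the tea group's +10%
advantage. Effect-recovery tests therefore plant one mechanism per
scenario with the others at zero; cohorts with joint effects are a valid
stress test of the pipeline but not a clean test of any single
mechanism's recovery.

Demographics are sampled at the published group means and proportions
(ages truncated to [60, 90], education to [0, 16] years); tea-frequency
records are constructed to be consistent with the planted group (NT
subjects score exactly 3; T subjects drink two teas at least 4–6 times a
week at both ages, scoring ≥ 9); neuropsychological scores are null by
default. The generator does **not** emulate BOLD autocorrelation,
hemodynamics, motion artifacts, or tractography error models; a green
recovery test establishes that the pipeline detects effects of the stated
size under well-behaved noise, not that it would under realistic
preprocessing residuals.

## Numerical choices and degenerate inputs

- Symmetry is validated to 1e-12; correlations are clipped to [−1, 1]
  before the negative-weight policy is applied.
- Zero-variance time series, non-positive volumes, asymmetric count
  matrices, and out-of-range frequency scales are hard errors naming the
  offending region, subject or field.
- A fully disconnected network has undefined L_w (error) but zero
  efficiency (defined); an edgeless network has C_w = 0.
- K for thresholding uses round-half-away-from-zero; base R's
  round-half-to-even would make K depend on representation parity.
- The exhaustive permutation p uses no +1 correction (the observed
  labeling is one of the enumerated assignments); the sampled p uses the
  +1/+1 convention.

## Known limitations

- Pearson correlation only; no partial correlation or tangent-space
  connectivity.
- No covariate adjustment inside the permutation scheme (age, education
  and sex are compared, not regressed out).
- The atlas ships *synthetic* mirror-symmetric region volumes for
  simulation; real analyses should supply measured volumes via
  `read_atlas()`.
- Printed-table statistics are reproduced from rounded summary data; the
  published age t of −0.92 is −0.911 when recomputed from the printed
  means and SDs, an inherent rounding limit, and the published prose and
  table even disagree on its sign.
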