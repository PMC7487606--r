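---
title: "Coordinate covariation analysis: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate covariation analysis: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocoa)
```

## The model

`cocoa` treats an epigenetic assay as a loci × samples signal matrix and
asks which *region sets* — functionally annotated interval collections
such as one transcription factor's binding sites — covary with a target
variable across samples. The analysis is two linear aggregations deep:

1. **Per-locus association.** Each locus gets a feature contribution
   score (FCS): its covariance, Pearson, or Spearman association with the
   target across samples. The assumption is that a regulatory program
   leaves a *coordinated* signature across the loci it touches, so
   per-locus associations, however noisy individually, reinforce when
   aggregated over the right interval collection.
2. **Per-set aggregation.** Nucleotide-resolution data (CpGs) are
   averaged within each region, then across regions, so a CpG-dense
   region does not dominate its set. Region-resolution data (peaks) use
   an overlap-proportion-weighted mean, weighting each data region by the
   fraction of the set region it covers.

Significance never comes from locus-level independence assumptions —
neighbouring CpGs are strongly correlated, and any parametric locus-level
test would be anticonservative. Instead the target's sample labels are
permuted and the *entire* pipeline is recomputed, giving each region set
its own null that inherits the data's correlation structure and that
set's coverage profile.

Targets may be supervised (phenotypes) or unsupervised (latent factors
from an internal PCA, or an external factorization supplied as a target
table). A precomputed locus × factor association matrix can be supplied
directly (`read_fcs_matrix()`), skipping step 1; permutation inference is
then unavailable, because a valid null requires recomputing associations
from raw signal under shuffled labels.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `metric` | auto: covariance (nucleotide), Pearson (region), Spearman (ordinal targets) | beta values are bounded in [0, 1], so covariance up-weights CpGs with larger absolute change; peak counts have incomparable ranges, so correlation puts them on one scale; Spearman for monotone non-linear relations |
| `use_abs` | `TRUE` | latent-factor signs are arbitrary, and methylation shifts in either direction are equally informative; signed scoring remains available |
| `stat` | `"mean"` | the median option is applied at *both* aggregation levels (region level and set level); applying one statistic symmetrically is the simplest consistent nesting, and on heterogeneous sets mean and median rankings agree strongly (tested) |
| `min_covered_regions` | 100 regions | sparsely assayed sets yield unstable scores; the filter requires at least 100 regions containing any data locus |
| `n_perm` | 300 | the gamma tail approximation extrapolates beyond the `1/(n_perm+1)` empirical floor, so a few hundred permutations suffice for screening |
| `total_width`, `n_bins` | 14 000 bp, 21 bins | profile windows wide enough to show flanking background around typical regulatory regions; `n_bins` is forced odd so offset 0 labels the center bin |

PCA scaling defaults off for methylation-like and on for count-like data,
mirroring the covariance/correlation metric choice.

## Numerical and procedural choices

* **Coordinates** are 0-based half-open everywhere internally (BED
  convention); 1-based CpG positions are converted on read
  (`p -> [p-1, p)`). Abutting intervals do not overlap and are not
  merged. Chromosome names match by exact string equality; a query and
  subject sharing *no* names triggers a loud warning rather than a silent
  empty result, and an opt-in `normalize_chrom` flag adds a `chr` prefix
  at I/O time.
* **Missing data** are handled pairwise per locus; loci with fewer than 3
  complete sample pairs get a missing FCS and are excluded from
  aggregation, with a reported count. A region whose loci all have
  missing FCS drops out of the outer average; a set with no coverage gets
  a missing score, not an error.
* **Degenerate targets.** A constant target is dropped with a warning at
  construction (correlation with it is undefined). Covariance against a
  constant vector arising *inside* a permutation replicate is 0 by
  definition, so degenerate shuffles cannot crash a run.
* **PCA sign convention**: each component is flipped so its
  largest-magnitude loading is positive — signs are otherwise arbitrary
  and would break reproducibility of signed scores (cosmetic under
  `use_abs`).
* **One shared permutation** of sample labels is applied to all target
  columns jointly per iteration, preserving cross-target correlation in
  the joint null and making multi-target runs reproducible from one seed.
  Permutations are drawn with R's generator from the supplied seed; with
  the seed fixed the whole inference is byte-identical across runs. When
  signal and targets are complete, all permutations are computed in a few
  matrix cross-products (rank-transforming first for Spearman, which is
  exact because ranks are permutation-equivariant); with missing values
  the association step loops per permutation. Both paths are tested to
  agree to 1e-12.
* **Empirical p-values** use the add-one convention
  `p = (1 + #{null >= obs}) / (1 + n_perm)`, with ties counting as
  exceedances: a finite permutation count cannot certify a smaller tail,
  so p is never 0.
* **Gamma fit** is the closed-form method of moments with the unbiased
  sample variance. The fit is *refused* (empirical fallback, recorded in
  the `p_source` column) when any null score is negative — with signed
  scoring the gamma support does not apply, and shifting the null would
  be a guess — or when the null variance is 0. Gamma p-values are floored
  at the smallest positive double; the documented caveat stands: accurate
  for moderate-to-large p, potentially overstating very small p.
* **BH correction** is applied per target across the region sets actually
  tested; missing p-values propagate and do not count as tests.
* **Ranking ties** break by region set name ascending, making output
  order deterministic.
* **Profile bins**: region center is `floor((start+end)/2)`; bin
  boundaries are `round(i * width / n_bins)` offsets, preserving total
  window coverage with integer edges. Nucleotide loci are assigned to
  bins by midpoint (exact for single-base loci); region data are weighted
  by overlap proportion against each bin, the same arithmetic as set
  scoring. Per-region bin values are averaged across regions (not pooled
  across loci), matching the scoring algorithm's nesting. Left and right
  flanks are kept distinct — asymmetry is informative. Regions wider than
  the window are skipped with a warning.

## What the synthetic generator does and does not emulate

`generate_dataset()` draws a standard-normal latent factor per sample,
plants disjoint regions whose loci follow
`effect_size * factor + N(0, noise_sd)` around a neutral baseline, adds
independent background loci, and scatters decoy region sets uniformly —
decoys may touch planted loci, which is part of a realistic null and
exercises the coverage filter. Methylation-like signal is squashed
through the logistic function (baseline 0.5), keeping the bounded (0, 1)
support that motivates the covariance metric without truncation
artifacts. Accessibility-like signal maps through a softplus around a
count-scale baseline of 8: strictly positive, and near-linear at that
baseline so a noiseless planted locus correlates essentially perfectly
with the factor — an exponential map would deliberately cap that
correlation near 0.76 and conflate scale nonlinearity with noise.

The canonical fixture (`default_planted_fixture()`): 100 samples, 20 000
background loci, 200 planted regions × 3 loci (width 500 bp), effect 1,
noise SD 1, 100 decoy sets × 200 regions on a 20-Mb chromosome, seed
20200907. At this density decoy sets have ~80 of 200 regions covered, so
validation analyses score the database with `min_covered_regions = 1`,
letting all 101 sets compete for rank and FDR; the default of 100 remains
the right filter for real, denser assays.

What is *not* emulated: array probe design and normalization artifacts,
batch effects, bimodal beta-value mixtures, copy-number confounding,
spatially autocorrelated background methylation, and library-size effects
in counts. Passing tests on this generator therefore demonstrate
correctness of the arithmetic and calibration of the permutation test
under clean conditions — not robustness to the technical structure of
real cohorts, where metric choice and preprocessing matter.

## Validation at desk scale

The shipped tests validate: both scorers against brute-force quadratic
oracles (200 random instances, 1e-10); calibration of the empirical
permutation p under the null, P(p ≤ 0.05) over 1000 independent
replicates at 2000 loci × 50 samples; gamma-vs-empirical agreement within
0.05 wherever empirical p ∈ [0.1, 0.9] on a 10^4-permutation null;
planted-set recovery (rank 1 of 101, q < 0.05) and its destruction under
pre-shuffled labels (20 repeats); and profile peak specificity against
200 decoy draws. These problem sizes are the package's chosen validation
conditions; they run in a few minutes on one CPU.

## Known limitations

* Gamma tail extrapolation can overstate the significance of very small
  p-values; rankings and the empirical fallback are the robust outputs.
* Region sets sharing regions have correlated scores; BH across sets
  controls FDR only in the usual dependent-test sense, and top-ranked
  sets should be read as a correlated group, not independent discoveries.
* Scores compare region sets *within* one analysis; they are not
  comparable across targets with different variances when covariance is
  the metric.
* No strand awareness, liftover, or assembly validation; inputs must
  share a genome build.
* With a precomputed FCS matrix no permutation null is possible;
  rankings are reported without p-values.
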