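---
title: "Cross-dataset similarity testing of microbiome group differences"
author: "starmaps package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-dataset similarity testing of microbiome group differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starmaps)
```

## The problem

Two microbiome surveys of the same biological contrast — say, treated
versus control animals in two labs, or two missions, or two sequencing
platforms — rarely share a processing pipeline, a primer set, or even a
taxon catalogue. Classical meta-analysis by intersecting lists of
differentially abundant taxa performs poorly here: 16S surveys uncover only
hundreds of taxa and a handful of confident hits, so list overlaps carry
little power. The test implemented in this package instead asks whether a
*linear combination of taxa* that captures the group difference in one
dataset (ds1) also captures the group difference in the other (ds2),
without ever calling individual taxa differential.

## The model and the test

Sequencing counts are compositional: the total depth of a sample is an
instrument artifact, so only relative information is meaningful. The
pipeline therefore works in the Aitchison geometry:

1. **Taxon matching.** The two tables are aligned to the union of their
   taxon identifiers; taxa seen in only one dataset are zero-filled in the
   other. Matching is by exact name — harmonizing nomenclatures is the
   caller's job, with `aggregateToLevel()` available to move both tables to
   a common rank first.
2. **Dirichlet point estimate.** Each sample's counts `c` are replaced by
   the mean of 1000 Monte Carlo draws from Dirichlet(`c` + 0.5). This is
   simultaneously the zero treatment (every taxon becomes strictly
   positive) and a shrinkage estimate of relative abundance; no other
   pseudo-count is applied anywhere. The closed-form mean
   `(c_i + 0.5) / sum(c_j + 0.5)` is available as `exact = TRUE`; it is the
   limit of the Monte Carlo mean and serves as the test oracle. Because the
   estimate is Monte Carlo, repeated runs with different seeds give very
   similar but not identical score plots; all component-test seeds are
   derived from one master seed and recorded in the result.
3. **ILR transform.** Compositions are mapped to (D−1)-dimensional
   Euclidean space with an isometric log-ratio basis. The basis is a fixed
   Helmert-type sequential binary partition in sorted taxon order. The
   choice is immaterial: every downstream quantity (distances, PCA
   eigenvalues, pseudo-F, p-values, direction cosines) is invariant under
   change of orthonormal log-ratio basis, a property the test suite
   asserts; fixing one particular basis merely makes runs deterministic.
4. **PCA on ds1 only.** A rotation is fitted to the centered, unscaled ILR
   coordinates of ds1, and the *same* affine map — ds1's center, ds1's
   loadings — projects ds2 onto ds1's axes. Centering ds2 by ds1's mean is
   one of several defensible conventions; since every downstream statistic
   is translation invariant, it cannot change any p-value or cosine. By
   default all axes with nonzero eigenvalue (relative tolerance 1e-10) are
   used; `nAxes = k` restricts to the first k for users who want the
   "first few PCs" reading.
5. **Three component tests.**
   * *Test 1*: one-way PERMANOVA of ds1's groups on ds1's scores.
   * *Test 2*: PERMANOVA of ds2's groups on the projected scores, **and** a
     taxon-matching permutation null in which the alignment of ds2's taxa
     to the union order is randomized, each replicate re-ILR-transformed
     and re-projected through the unchanged model. The larger of the two
     p-values is kept. The second null is what makes the test specific:
     strong group structure in ds2 that lives on a *different* combination
     of taxa survives taxon permutation and therefore fails it. Its null
     statistic is the pseudo-F itself (not a nested p-value).
   * *Test 3*: the group-difference direction (second-named group centroid
     minus first-named) is drawn in each dataset and the cosine of the
     angle between them computed; cosθ = 1 means same direction, −1
     opposite, 0 incomparable. A bootstrap — resampling samples with
     replacement within each group of each dataset — yields the two-sided
     sign-crossing p-value `2 · min(Pr(cosθ* ≤ 0), Pr(cosθ* ≥ 0))`, capped
     at 1.
6. **Omnibus.** Similarity requires all three conditions simultaneously, so
   the rejection region is the intersection of the component rejection
   regions and the omnibus p-value is the supremum — in practice the
   maximum — of the component p-values (intersection–union test). The IUT
   is level-α and typically conservative, which the type-I-error checks
   reflect.

## PERMANOVA internals

The one-way pseudo-F is computed from coordinates,
`F = (SS_between/(a−1)) / (SS_within/(n−a))`, which for Euclidean
distances equals the distance-based formulation (centroid identity). When
the number of distinct group labellings is at most `nPerm`, every
labelling is enumerated exactly once and the p-value is the exact
fraction with `F* ≥ F_obs`; otherwise `nPerm` labellings are sampled and
the observed one is counted in both numerator and denominator (so
p ≥ 1/(nPerm+1), never zero). Ties count toward the p-value, guarded by a
small relative epsilon so floating-point noise cannot drop a genuinely
tied labelling. One consequence worth knowing: with two equal-sized
groups, swapping the group names produces a distinct labelling with an
identical F, so the smallest achievable exhaustive p is 2/(number of
labellings) — e.g. 2/70 ≈ 0.029 at 4+4, 2/924 ≈ 0.0022 at 6+6. Designs
below roughly five per group simply cannot produce very small
segregation p-values.

## Bootstrap design choices

The direction bootstrap refits the PCA on each resampled ds1 by default
(`refitBoot = TRUE`), propagating the uncertainty of the axes themselves;
`refitBoot = FALSE` holds the fitted model fixed, a cheaper and slightly
anticonservative approximation. Because the bootstrap resamples whole
samples, and the Dirichlet point estimate is a per-sample statistic, each
replicate's point estimates are exactly the cached per-sample values; the
implementation therefore resamples rows of the cached ILR matrix and
refits the rotation through the n×n Gram matrix, which is algebraically
identical to recomputing the pipeline on the resampled counts at the same
Dirichlet draws. Replicates where a resampled dataset collapses (zero
direction, or no axis above tolerance) yield an undefined cosine and are
excluded from the two tail fractions; if the *observed* direction in
either dataset is zero, the cosine is undefined and p3 is reported as 1.

Bootstrap indices are drawn in a canonical (group, sample-id) order, so
reordering input columns cannot change p3 at a fixed seed. One Dirichlet
seed, derived from the master seed, is shared by both datasets; identical
inputs then receive identical Monte Carlo draws, which is what makes
`starmaps(ds1, ds1, ...)` return cosθ = 1 exactly rather than 1 minus
Monte Carlo noise.

## The simulation framework

`simulatePair()` generates dataset pairs of known truth, emulating a
published evaluation design:

* A **template** fixes a species-abundance law and a sequencing-depth
  sampler. The default is parametric — D = 200 species with log-normal
  rank abundance (sdlog = 2, giving the heavy-tailed, uneven profile
  typical of fecal communities) and log-normal depths with median 30,000
  reads truncated to [10³, 10⁶] — chosen so that zero-inflation and
  depth variation resemble a real 16S survey. Any user count table can be
  supplied instead via `templateFromCounts()`, which uses the pooled
  relative abundances and the observed depth pool.
* Each dataset has two groups of N multinomial samples. 10% of species
  (`propDA`) are differentially abundant: their template proportions are
  multiplied by `2^log2fc` in group 2, then renormalized.
* ds1 applies a constant `log2fcMean`; ds2 draws per-species effects from
  Normal(`log2fcMean`, s²), applied as drawn (no truncation, so large s
  can flip signs — intended). *Similar* pairs share the differentially
  abundant species set; *dissimilar* pairs use disjoint sets of equal
  size. A fraction 1−overlap of ds2's species names receives an "xx"
  suffix so they cannot be matched, emulating catalogue mismatch between
  studies.

`evaluatePerformance()` runs the similarity test on `nPairs` pairs
(roughly 1:1 similar:dissimilar), sweeps the omnibus-p threshold, and
reports sensitivity, specificity and ROC points. Every pair derives its
seed from the spec's master seed, so evaluations replay identically and a
parallel implementation would be bound to the same per-pair results.

## What the simulations do and do not show

The generator captures compositionality, sparsity, depth variation, and
effect-size heterogeneity between studies. It does not model taxonomic
misannotation beyond name masking, phylogenetic correlation between
differentially abundant taxa, batch-specific extraction or primer biases,
or overdispersion beyond the multinomial (no Dirichlet-multinomial noise
layer). Passing the performance checks therefore demonstrates the
statistical machinery under controlled, favorable-but-plausible
conditions; it does not certify power on any particular pair of real
datasets.

## Problem sizes and numerical choices

The test suite exercises the performance properties at 200 pairs per
condition with 500 permutations/bootstraps per component test, and the
full-strength defaults (10,000 permutations/bootstraps, 1000 Dirichlet
draws) on single comparisons; these sizes give binomial standard errors
of a few percent on sensitivity/specificity estimates, which matches the
tolerances asserted. Eigenvalues are kept at a relative tolerance of
1e-10; permutation tie comparisons use a relative epsilon of 1e-9 in
favor of the null; compositions are validated to close to 1 within 1e-9.
Degenerate inputs — a dataset with no shared taxa, a zero within-group
sum of squares (pseudo-F = ∞), single-sample bootstrap groups — are
allowed and flagged with messages rather than errors where the
computation remains defined.

## Known limitations

* One ordered group pair per call; multi-group designs must be compared
  pairwise, and the caller is responsible for supplying both pairs in the
  same scientific orientation (the sign of cosθ is meaningless
  otherwise).
* Only the one-way PERMANOVA design is provided; multi-factor variance
  decomposition is out of scope.
* Exact-identifier taxon matching; no fuzzy nomenclature harmonization.
* Small designs are limited by permutation granularity (see above), and
  the omnibus p can never undercut its most granular component.
* The taxon-matching null is powerless for a literal self-comparison
  (`starmaps(ds1, ds1)`): permuting taxa is an isometry of the Aitchison
  geometry, and because the pseudo-F is a variance *ratio*, the fraction
  of variance a random projection retains cancels between numerator and
  denominator — the permuted F exceeds the observed one about half the
  time no matter how separated the groups are, so p2_taxon sits near 0.5
  and the omnibus follows it. This is a property of the test's design,
  not a defect: the taxon null asks whether ds2's signal rides on ds1's
  *fitted* axes beyond what generic geometry explains, and for the
  identical dataset nothing exceeds generic geometry. Self-comparison is
  still useful as a check of the direction machinery (cosθ = 1 exactly,
  p1 = p2_sample); the meaningful positive control is an *independent*
  replicate pair, which the simulation framework shows is called similar
  with high sensitivity at strong effects.
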