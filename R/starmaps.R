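## The cross-dataset similarity test: taxon matching, PCA projection fitted
## on the first dataset, three component tests, intersection-union omnibus.

## ---- taxon matching -------------------------------------------------------

#' Match two count tables into their union taxon space
#'
#' Aligns both tables to the union of their taxon identifiers so the samples
#' of the two datasets live in the same taxon space. Taxa detected in only
#' one dataset are filled with zero counts in the other. The union order is
#' deterministic: ds1's taxa in ds1 order, then taxa new to ds2 in ds2
#' order. Matching is by exact identifier; aggregation to a common rank
#' beforehand is the caller's job (see [aggregateToLevel()]).
#'
#' @param ds1,ds2 [MicrobiomeCounts-class] objects at a comparable
#'   taxonomic level.
#' @return A [MatchedPair-class]. An empty taxon intersection is allowed but
#'   reported with a message (the taxon-matching null is then meaningless).
#' @export
matchTaxa <- function(ds1, ds2) {
  c1 <- counts(ds1); c2 <- counts(ds2)
  union <- c(rownames(c1), setdiff(rownames(c2), rownames(c1)))
  a1 <- matrix(0, length(union), ncol(c1),
               dimnames = list(union, colnames(c1)))
  a2 <- matrix(0, length(union), ncol(c2),
               dimnames = list(union, colnames(c2)))
  a1[rownames(c1), ] <- c1
  a2[rownames(c2), ] <- c2
  presence <- factor(ifelse(union %in% rownames(c1),
                            ifelse(union %in% rownames(c2), "both",
                                   "ds1_only"),
                            "ds2_only"),
                     levels = c("ds1_only", "ds2_only", "both"))
  if (!any(presence == "both"))
    message("matchTaxa: the two datasets share no taxa")
  methods::new("MatchedPair",
               ds1 = MicrobiomeCounts(a1, sampleGroups(ds1),
                                      level = taxonLevel(ds1)),
               ds2 = MicrobiomeCounts(a2, sampleGroups(ds2),
                                      level = taxonLevel(ds2)),
               unionTaxa = union, presence = presence)
}

## ---- projection -----------------------------------------------------------

## PCA of centered, unscaled ILR coordinates. Axis policy: "all" keeps every
## axis whose eigenvalue exceeds 1e-10 x the largest; an integer keeps the
## first k of those.
.fitPca <- function(ilr1, nAxes) {
  n1 <- nrow(ilr1)
  center <- colMeans(ilr1)
  sv <- svd(sweep(ilr1, 2, center))
  eig <- sv$d^2 / (n1 - 1)
  keep <- which(eig > 1e-10 * max(eig, .Machine$double.xmin))
  if (!identical(nAxes, "all"))
    keep <- keep[seq_len(min(as.integer(nAxes), length(keep)))]
  rot <- sv$v[, keep, drop = FALSE]
  colnames(rot) <- paste0("PC", seq_along(keep))
  methods::new("ProjectionModel", center = center, rotation = rot,
               eigenvalues = eig[keep], basis = matrix(0, 0, 0))
}

#' Fit the PCA projection on the first dataset
#'
#' Runs the compositional pipeline (Dirichlet point estimate, ILR) on the
#' first dataset of a matched pair and fits a PCA on the centered, unscaled
#' ILR coordinates. The second dataset plays no part in the fit; it is later
#' sent through the identical affine map by [projectSamples()].
#'
#' @param pair a [MatchedPair-class] from [matchTaxa()].
#' @param nDraws,offset,seed,exact passed to [dirichletPointEstimate()].
#' @param nAxes `"all"` (every axis with nonzero eigenvalue, relative
#'   tolerance 1e-10) or an integer k for the first k axes.
#' @param basis optional shared ILR contrast matrix over the union taxa;
#'   default [ilrBasis()] on the union identifiers.
#' @return A [ProjectionModel-class].
#' @export
fitProjection <- function(pair, nDraws = 1000, offset = 0.5, seed = NULL,
                          exact = FALSE, nAxes = "all", basis = NULL) {
  if (is.null(basis)) basis <- ilrBasis(pair@unionTaxa)
  comp1 <- dirichletPointEstimate(counts(pair@ds1), nDraws, offset,
                                  seed = seed, exact = exact)
  ilr1 <- ilrCoords(ilrTransform(comp1, basis))
  if (nrow(ilr1) < 3L) stop("need at least 3 samples in ds1")
  model <- .fitPca(ilr1, nAxes)
  model@basis <- basis
  methods::validObject(model)
  model
}

#' Project a dataset of a matched pair onto fitted PC axes
#'
#' Applies the affine map fitted on the first dataset,
#' `scores = (ilr - center) %*% rotation`, to either dataset of the pair.
#' Both datasets are centered with the first dataset's ILR mean; because
#' every downstream statistic is translation invariant, this choice cannot
#' affect any p-value or direction cosine.
#'
#' @param model a [ProjectionModel-class] fitted on the same pair and basis.
#' @param pair the [MatchedPair-class] the model was fitted on.
#' @param which `"ds1"` or `"ds2"`.
#' @param nDraws,offset,seed,exact passed to [dirichletPointEstimate()]; use
#'   the same values as in [fitProjection()] to reproduce its scores.
#' @return samples-by-axes score matrix.
#' @export
projectSamples <- function(model, pair, which = c("ds2", "ds1"),
                           nDraws = 1000, offset = 0.5, seed = NULL,
                           exact = FALSE) {
  which <- match.arg(which)
  ds <- if (which == "ds1") pair@ds1 else pair@ds2
  if (nrow(model@basis) != nrow(counts(ds)))
    stop("model basis does not match the pair's union taxon space")
  comp <- dirichletPointEstimate(counts(ds), nDraws, offset,
                                 seed = seed, exact = exact)
  ilr <- ilrCoords(ilrTransform(comp, model@basis))
  sweep(ilr, 2, model@center) %*% model@rotation
}

## ---- component tests ------------------------------------------------------

#' Component test: group segregation of dataset 1
#'
#' PERMANOVA of the first dataset's groups on its own PC scores.
#'
#' @param scores1 score matrix from the fitted projection.
#' @param groups1 group label per row.
#' @param nPerm,seed,exhaustive passed to [permanova()].
#' @return A [PermanovaResult-class].
#' @export
testDs1Segregation <- function(scores1, groups1, nPerm = 10000, seed = NULL,
                               exhaustive = "auto") {
  permanova(scores1, groups1, nPerm = nPerm, seed = seed,
            exhaustive = exhaustive)
}

## Taxon-matching permutation null: permute which ds2 taxa align to the
## union order, re-ILR and re-project through the unchanged model, and
## compare the resulting pseudo-F with the observed one. Works on the CLR
## matrix: permuting composition rows permutes CLR columns (the geometric
## mean is permutation invariant), so each replicate is
## clr2[, perm] %*% basis %*% rotation, i.e. clr2 %*% W[inv(perm), ].
.test2Taxon <- function(clr2, W, c0, labels2, fObs, nPerm, seed) {
  f <- factor(labels2)
  count <- .withSeed(seed, function()
    .taxonPermCount(clr2, W, c0, as.integer(f), as.numeric(table(f)),
                    as.integer(nPerm), fObs))
  (1 + count) / (nPerm + 1)
}

#' Component test: group segregation of dataset 2 on dataset 1's axes
#'
#' Two nulls are evaluated for the projected second dataset and the larger
#' p-value is kept: (i) the usual PERMANOVA sample-label permutations, and
#' (ii) a taxon-matching permutation test in which the alignment of the
#' second dataset's taxa to the union taxon order is randomized, each
#' replicate re-ILR-transformed and re-projected through the unchanged
#' model. The second null checks that the specific linear combination of
#' taxa fitted on dataset 1 — not just any multivariate structure — carries
#' the group signal; its null statistic is the pseudo-F itself, avoiding a
#' nested permutation test.
#'
#' @param model fitted [ProjectionModel-class].
#' @param pair the [MatchedPair-class] the model was fitted on.
#' @param nPerm permutations per null.
#' @param seed master seed for this test (two child seeds are derived).
#' @param exhaustive passed to the sample-permutation PERMANOVA.
#' @param nDraws,offset,exact passed to [dirichletPointEstimate()] for the
#'   second dataset.
#' @return list with `p2Sample`, `p2Taxon`, `p2 = max` and the observed
#'   pseudo-F.
#' @export
testDs2Segregation <- function(model, pair, nPerm = 10000, seed = NULL,
                               exhaustive = "auto", nDraws = 1000,
                               offset = 0.5, exact = FALSE) {
  seed <- .resolveSeed(seed)
  seeds <- .deriveSeeds(seed, 3)
  comp2 <- dirichletPointEstimate(counts(pair@ds2), nDraws, offset,
                                  seed = seeds[1], exact = exact)
  clr2 <- clrTransform(comp2)
  groups2 <- sampleGroups(pair@ds2)
  .test2core(clr2, clr2 %*% model@basis, model, groups2, nPerm,
             seeds[2], seeds[3], exhaustive)
}

.test2core <- function(clr2, ilr2, model, groups2, nPerm, seedSample,
                       seedTaxon, exhaustive) {
  W <- model@basis %*% model@rotation
  c0 <- drop(model@center %*% model@rotation)
  ## observed scores via the same arithmetic used for ds1, so that
  ## identical inputs give bitwise identical score matrices
  scores2 <- sweep(ilr2, 2, model@center) %*% model@rotation
  r2s <- permanova(scores2, groups2, nPerm = nPerm, seed = seedSample,
                   exhaustive = exhaustive)
  fObs <- pseudoF(r2s)
  p2t <- .test2Taxon(clr2, W, c0, groups2, fObs, nPerm, seedTaxon)
  list(p2Sample = pValue(r2s), p2Taxon = p2t,
       p2 = max(pValue(r2s), p2t), statistic = fObs, scores2 = scores2)
}

#' Group-difference direction in score space
#'
#' The line through the two group centroids, oriented second-named minus
#' first-named: `centroid(groupPair[2]) - centroid(groupPair[1])`. Supply
#' the pair in the same scientific orientation for both datasets (e.g.
#' treated vs control in each) so the sign of the direction cosine is
#' meaningful.
#'
#' @param scores samples-by-axes score matrix.
#' @param groups group label per row.
#' @param groupPair ordered pair of group names.
#' @return numeric direction vector (length = number of axes).
#' @export
groupDirection <- function(scores, groups, groupPair) {
  stopifnot(length(groupPair) == 2L)
  missing <- setdiff(groupPair, unique(as.character(groups)))
  if (length(missing))
    stop("unknown group name(s): ", paste(missing, collapse = ", "))
  scores <- as.matrix(scores)
  m2 <- colMeans(scores[groups == groupPair[2], , drop = FALSE])
  m1 <- colMeans(scores[groups == groupPair[1], , drop = FALSE])
  m2 - m1
}

## Bootstrap for the direction test. Operates on cached ILR matrices; sample
## indices are taken in a canonical (group, id) order so the result does not
## depend on input column order. With refit = TRUE the PCA model is refitted
## on each resampled ds1 (propagating estimation uncertainty in the axes);
## with refit = FALSE the fitted model is held fixed (fast approximation).
.test3Boot <- function(ilr1, ilr2, groups1, groups2, pair1, pair2,
                       model, nBoot, seed, refit, nAxes) {
  ord1 <- .stableOrder(paste(match(groups1, pair1), rownames(ilr1)))
  ord2 <- .stableOrder(paste(match(groups2, pair2), rownames(ilr2)))
  X1 <- ilr1[ord1, , drop = FALSE]; g1 <- groups1[ord1]
  X2 <- ilr2[ord2, , drop = FALSE]; g2 <- groups2[ord2]
  idx1 <- lapply(pair1, function(g) which(g1 == g))
  idx2 <- lapply(pair2, function(g) which(g2 == g))
  if (any(lengths(c(idx1, idx2)) == 1L))
    message("direction bootstrap: a group has a single sample; ",
            "its resamples are degenerate")
  kAxes <- if (identical(nAxes, "all")) 0L else as.integer(nAxes)
  cos <- .withSeed(seed, function()
    .bootCosine(X1, X2, idx1[[1]], idx1[[2]], idx2[[1]], idx2[[2]],
                as.integer(nBoot), isTRUE(refit), kAxes, model@rotation))
  ok <- !is.na(cos)
  if (!any(ok)) return(list(p3 = 1, cosBoot = cos))
  p3 <- min(1, 2 * min(mean(cos[ok] <= 0), mean(cos[ok] >= 0)))
  list(p3 = p3, cosBoot = cos)
}

#' Component test: bootstrap test of direction similarity
#'
#' Estimates whether zero is a plausible value of the direction cosine by
#' resampling samples with replacement within each group of each dataset,
#' recomputing both group-difference directions (and, by default, refitting
#' the PCA model on the resampled first dataset) and taking the two-sided
#' sign-crossing p-value `2 * min(Pr(cos* <= 0), Pr(cos* >= 0))`, capped at
#' 1. If the observed direction in either dataset is zero the cosine is
#' undefined and `p3 = 1` is returned.
#'
#' @param model fitted [ProjectionModel-class].
#' @param pair the [MatchedPair-class] the model was fitted on.
#' @param groupPair1,groupPair2 ordered group pairs (see
#'   [groupDirection()]).
#' @param nBoot bootstrap replicates.
#' @param seed master seed for this test.
#' @param refit refit the PCA per replicate (default) or hold the model
#'   fixed (fast approximation).
#' @param nAxes axis policy used when refitting (as in [fitProjection()]).
#' @param nDraws,offset,exact passed to [dirichletPointEstimate()].
#' @return list with observed `cosTheta`, `p3` and the bootstrap cosines.
#' @export
testDirection <- function(model, pair, groupPair1, groupPair2 = groupPair1,
                          nBoot = 10000, seed = NULL, refit = TRUE,
                          nAxes = "all", nDraws = 1000, offset = 0.5,
                          exact = FALSE) {
  seed <- .resolveSeed(seed)
  seeds <- .deriveSeeds(seed, 2)
  comp1 <- dirichletPointEstimate(counts(pair@ds1), nDraws, offset,
                                  seed = seeds[1], exact = exact)
  comp2 <- dirichletPointEstimate(counts(pair@ds2), nDraws, offset,
                                  seed = seeds[1], exact = exact)
  ilr1 <- ilrCoords(ilrTransform(comp1, model@basis))
  ilr2 <- ilrCoords(ilrTransform(comp2, model@basis))
  .test3core(ilr1, ilr2, sampleGroups(pair@ds1), sampleGroups(pair@ds2),
             groupPair1, groupPair2, model, nBoot, seeds[2], refit, nAxes)
}

.test3core <- function(ilr1, ilr2, groups1, groups2, pair1, pair2, model,
                       nBoot, seed, refit, nAxes) {
  s1 <- sweep(ilr1, 2, model@center) %*% model@rotation
  s2 <- sweep(ilr2, 2, model@center) %*% model@rotation
  d1 <- groupDirection(s1, groups1, pair1)
  d2 <- groupDirection(s2, groups2, pair2)
  cosObs <- cosTheta(d1, d2)
  if (is.na(cosObs)) {
    message("direction test: a group-difference direction has zero length; ",
            "p3 set to 1")
    return(list(cosTheta = NA_real_, p3 = 1, cosBoot = numeric(0)))
  }
  bt <- .test3Boot(ilr1, ilr2, groups1, groups2, pair1, pair2, model,
                   nBoot, seed, refit, nAxes)
  list(cosTheta = cosObs, p3 = bt$p3, cosBoot = bt$cosBoot)
}

## ---- orchestration --------------------------------------------------------

#' Cross-dataset similarity test for microbiome group differences
#'
#' Tests whether the between-group difference pattern of `ds1` is reproduced
#' in `ds2`. The pipeline: subset both tables to the compared groups, match
#' taxa into the union space, estimate strictly positive compositions
#' (Monte Carlo Dirichlet point estimates), ILR-transform, fit PCA on `ds1`
#' only and project `ds2` onto the same axes, then run three component
#' tests: (1) PERMANOVA of `ds1` segregation, (2) PERMANOVA of `ds2`
#' segregation plus a taxon-matching permutation test (larger p kept), and
#' (3) a bootstrap test on the cosine of the angle between the two
#' group-difference directions. Because similarity requires all three to
#' hold simultaneously, the omnibus p-value is the intersection-union test
#' supremum `max(p1, p2, p3)`.
#'
#' Dirichlet point estimates are computed once per call (permutation nulls
#' reshuffle labels or taxon alignment, not the data); identical inputs get
#' identical Monte Carlo draws, so `starmaps(ds1, ds1, ...)` returns a
#' direction cosine of exactly 1.
#'
#' @param ds1,ds2 [MicrobiomeCounts-class] tables at a comparable taxonomic
#'   level.
#' @param groupPair1 ordered pair of group names compared in `ds1`
#'   (direction is second minus first).
#' @param groupPair2 ordered pair for `ds2`, in the same scientific
#'   orientation; defaults to `groupPair1`.
#' @param nPerm permutations per permutation test.
#' @param nBoot bootstrap replicates for the direction test.
#' @param nDraws Monte Carlo Dirichlet instances per sample.
#' @param offset Dirichlet pseudo-count offset.
#' @param nAxes `"all"` or an integer number of leading PC axes.
#' @param seed master seed; all component seeds are derived from it and
#'   recorded in the result. `NULL` draws one.
#' @param exact use closed-form Dirichlet means (deterministic pipeline).
#' @param refitBoot refit the PCA per bootstrap replicate (default TRUE).
#' @param exhaustive permutation mode for the sample-label PERMANOVAs
#'   (`"auto"`, `"always"`, `"never"`).
#' @param basis optional shared ILR basis over the union taxa (results are
#'   invariant to this choice).
#' @return A [StarmapsResult-class].
#' @examples
#' pair <- exampleCountPair()
#' res <- starmaps(pair$ds1, pair$ds2, c("g1", "g2"),
#'                 nPerm = 500, nBoot = 500, nDraws = 100, seed = 1)
#' res
#' @export
starmaps <- function(ds1, ds2, groupPair1, groupPair2 = groupPair1,
                     nPerm = 10000, nBoot = 10000, nDraws = 1000,
                     offset = 0.5, nAxes = "all", seed = NULL,
                     exact = FALSE, refitBoot = TRUE,
                     exhaustive = "auto", basis = NULL) {
  stopifnot(length(groupPair1) == 2L, length(groupPair2) == 2L)
  ds1 <- .subsetGroups(ds1, groupPair1)
  ds2 <- .subsetGroups(ds2, groupPair2)
  if (any(table(sampleGroups(ds1)) < 2L) ||
      any(table(sampleGroups(ds2)) < 2L))
    stop("every compared group needs at least 2 samples")
  seed <- .resolveSeed(seed)
  seeds <- .deriveSeeds(seed, 5)  # dirichlet, p1, p2 sample, p2 taxon, boot

  pair <- matchTaxa(ds1, ds2)
  if (is.null(basis)) basis <- ilrBasis(pair@unionTaxa)

  ## one Dirichlet seed shared by both datasets: identical inputs then give
  ## identical point estimates (self-comparison yields cos theta = 1)
  comp1 <- dirichletPointEstimate(counts(pair@ds1), nDraws, offset,
                                  seed = seeds[1], exact = exact)
  comp2 <- dirichletPointEstimate(counts(pair@ds2), nDraws, offset,
                                  seed = seeds[1], exact = exact)
  clr1 <- clrTransform(comp1)
  clr2 <- clrTransform(comp2)
  ilr1 <- clr1 %*% basis
  ilr2 <- clr2 %*% basis

  model <- .fitPca(ilr1, nAxes)
  model@basis <- basis
  scores1 <- sweep(ilr1, 2, model@center) %*% model@rotation
  colnames(scores1) <- colnames(model@rotation)

  g1 <- sampleGroups(pair@ds1)
  g2 <- sampleGroups(pair@ds2)

  r1 <- permanova(scores1, g1, nPerm = nPerm, seed = seeds[2],
                  exhaustive = exhaustive)
  t2 <- .test2core(clr2, ilr2, model, g2, nPerm, seeds[3], seeds[4],
                   exhaustive)
  scores2 <- t2$scores2
  colnames(scores2) <- colnames(model@rotation)
  t3 <- .test3core(ilr1, ilr2, g1, g2, groupPair1, groupPair2, model,
                   nBoot, seeds[5], refitBoot, nAxes)

  omnibus <- max(pValue(r1), t2$p2, t3$p3)
  methods::new(
    "StarmapsResult",
    p1 = pValue(r1), p2Sample = t2$p2Sample, p2Taxon = t2$p2Taxon,
    p2 = t2$p2, cosTheta = t3$cosTheta, p3 = t3$p3, omnibusP = omnibus,
    scores1 = scores1, scores2 = scores2,
    nAxes = ncol(model@rotation),
    settings = list(
      schema = "starmaps-result/1",
      seed = seed,
      seedDirichlet = seeds[1], seedP1 = seeds[2], seedP2Sample = seeds[3],
      seedP2Taxon = seeds[4], seedBoot = seeds[5],
      nPerm = nPerm, nBoot = nBoot, nDraws = nDraws, offset = offset,
      exact = exact, refitBoot = refitBoot, exhaustiveRequested = exhaustive,
      modeP1 = r1@mode, nAxesRequested = nAxes,
      groupPair1 = groupPair1, groupPair2 = groupPair2,
      nUnionTaxa = length(pair@unionTaxa),
      nSharedTaxa = sum(pair@presence == "both"),
      samples1 = colnames(counts(pair@ds1)),
      samples2 = colnames(counts(pair@ds2))))
}

#' Similarity call at a significance level
#'
#' A convenience presentation of the omnibus result: the two datasets are
#' called similar when the omnibus p falls below `alpha`. The threshold is a
#' reporting default, not part of the test.
#'
#' @param result a [StarmapsResult-class].
#' @param alpha significance level.
#' @return logical.
#' @export
isSimilar <- function(result, alpha = 0.05) {
  omnibusP(result) < alpha
}
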