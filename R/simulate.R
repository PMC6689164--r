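## Simulation framework: paired datasets with known similar/dissimilar
## group-difference patterns, and sensitivity/specificity/ROC evaluation of
## the similarity call.

#' Parametric species-abundance template
#'
#' Builds a heavy-tailed rank-abundance law (log-normal ranks, sorted
#' non-increasing, normalized) over `D` species plus a log-normal
#' sequencing-depth sampler truncated to `[depthMin, depthMax]`. This
#' parametric template stands in for an empirical fecal-community profile;
#' any user count table can be used instead via [templateFromCounts()].
#'
#' @param D number of species (>= 10).
#' @param propSdlog standard deviation of the log-normal rank-abundance law
#'   (larger = more uneven community).
#' @param depthMedian median sequencing depth.
#' @param depthSdlog log-scale spread of depths.
#' @param depthMin,depthMax truncation bounds for depths.
#' @param seed integer seed.
#' @return A [Template-class].
#' @examples
#' tpl <- makeTemplate(D = 50, seed = 1)
#' tpl
#' @export
makeTemplate <- function(D = 200, propSdlog = 2, depthMedian = 3e4,
                         depthSdlog = 0.6, depthMin = 1000,
                         depthMax = 1e6, seed = NULL) {
  if (D < 10) stop("D must be >= 10")
  if (propSdlog <= 0 || depthSdlog < 0 || depthMedian < depthMin ||
      depthMedian > depthMax)
    stop("invalid template shape parameters")
  seed <- .resolveSeed(seed)
  p <- .withSeed(seed, function() sort(rlnorm(D, 0, propSdlog),
                                       decreasing = TRUE))
  p <- p / sum(p)
  names(p) <- sprintf("sp%04d", seq_len(D))
  methods::new("Template", speciesProps = p,
               depths = list(type = "lognormal",
                             meanlog = log(depthMedian),
                             sdlog = depthSdlog,
                             min = depthMin, max = depthMax))
}

#' Empirical template from a user count table
#'
#' Uses the overall relative abundance of each taxon (pooled across samples)
#' as the species-abundance law and the observed per-sample totals as the
#' depth pool (sampled with replacement). Taxa with zero total count are
#' dropped.
#'
#' @param x a [MicrobiomeCounts-class] object or count matrix.
#' @return A [Template-class].
#' @export
templateFromCounts <- function(x) {
  m <- if (methods::is(x, "MicrobiomeCounts")) counts(x) else as.matrix(x)
  tot <- rowSums(m)
  tot <- tot[tot > 0]
  if (length(tot) < 2) stop("template needs at least two observed taxa")
  methods::new("Template", speciesProps = tot / sum(tot),
               depths = list(type = "empirical",
                             depths = as.numeric(colSums(m))))
}

.drawDepths <- function(template, n) {
  d <- template@depths
  if (d$type == "lognormal") {
    x <- rlnorm(n, d$meanlog, d$sdlog)
    as.integer(round(pmin(pmax(x, d$min), d$max)))
  } else {
    as.integer(sample(d$depths, n, replace = TRUE))
  }
}

## Group-2 species proportions after applying per-species fold changes:
## multiply each differentially abundant species' proportion by 2^log2fc,
## then renormalize.
.effectProps <- function(props, log2fc) {
  p <- props
  if (length(log2fc)) {
    missing <- setdiff(names(log2fc), names(p))
    if (length(missing))
      stop("fold-change species not in template: ",
           paste(missing, collapse = ", "))
    p[names(log2fc)] <- p[names(log2fc)] * 2^log2fc
  }
  p / sum(p)
}

#' Simulate one two-group dataset from a template
#'
#' Draws `2 * N` multinomial samples (two groups of `N`) at sequencing
#' depths drawn from the template's depth sampler. Group `g1` samples use
#' the template proportions; group `g2` samples use the proportions after
#' multiplying each differentially abundant species by `2^log2fc` and
#' renormalizing.
#'
#' @param template a [Template-class].
#' @param N samples per group.
#' @param log2fc named numeric vector of per-species log2 fold changes
#'   (names must be template species); may be empty for a null dataset.
#' @param seed integer seed.
#' @param sampleIdPrefix prefix for sample identifiers.
#' @return A [MicrobiomeCounts-class] with groups `g1`, `g2`.
#' @export
simulateDataset <- function(template, N, log2fc = numeric(0), seed = NULL,
                            sampleIdPrefix = "s") {
  if (N < 2) stop("N must be >= 2")
  seed <- .resolveSeed(seed)
  p1 <- template@speciesProps
  p2 <- .effectProps(p1, log2fc)
  .withSeed(seed, function() {
    depths <- .drawDepths(template, 2L * N)
    cts <- matrix(0, length(p1), 2L * N,
                  dimnames = list(names(p1),
                                  sprintf("%s%02d", sampleIdPrefix,
                                          seq_len(2L * N))))
    for (j in seq_len(2L * N)) {
      pr <- if (j <= N) p1 else p2
      cts[, j] <- rmultinom(1, depths[j], pr)
    }
    MicrobiomeCounts(cts, groups = rep(c("g1", "g2"), each = N),
                     level = "species")
  })
}

#' Construct a simulation condition
#'
#' @param nPerGroup samples per group (N).
#' @param log2fcMean mean log2 fold change (constant in dataset 1).
#' @param log2fcSd standard deviation s of the per-species log2 fold change
#'   drawn for dataset 2 (`Normal(log2fcMean, s^2)`, applied as drawn, no
#'   truncation).
#' @param overlap proportion of species whose names match between the
#'   datasets; a fraction `1 - overlap` of dataset 2's species names get an
#'   `"xx"` suffix so they cannot be matched.
#' @param propDA proportion of differentially abundant species.
#' @param nPairs number of pairs for [evaluatePerformance()].
#' @param template a [Template-class]; default [makeTemplate()] with
#'   `seed` derived from `seed`.
#' @param seed master seed.
#' @return A [SimulationSpec-class].
#' @export
SimulationSpec <- function(nPerGroup = 6, log2fcMean = 2, log2fcSd = 0,
                           overlap = 1, propDA = 0.10, nPairs = 200,
                           template = NULL, seed = NULL) {
  seed <- .resolveSeed(seed)
  if (is.null(template))
    template <- makeTemplate(seed = .deriveSeeds(seed, 1))
  methods::new("SimulationSpec", nPerGroup = as.integer(nPerGroup),
               log2fcMean = as.numeric(log2fcMean),
               log2fcSd = as.numeric(log2fcSd),
               overlap = as.numeric(overlap), propDA = as.numeric(propDA),
               nPairs = as.integer(nPairs), template = template,
               seed = seed)
}

#' Simulate a dataset pair with known similarity truth
#'
#' Dataset 1 applies a constant `log2fcMean` to a random set of
#' `ceiling(propDA * D)` species. Dataset 2 applies per-species effects
#' drawn from `Normal(log2fcMean, log2fcSd^2)` to the same species set
#' (`truth = "similar"`) or to a disjoint set of the same size
#' (`truth = "dissimilar"`). A fraction `1 - overlap` of dataset 2's
#' species names is masked with an `"xx"` suffix so they cannot be matched
#' across datasets.
#'
#' @param spec a [SimulationSpec-class].
#' @param truth `"similar"` or `"dissimilar"`.
#' @param seed seed for this pair (default: the spec's seed).
#' @return A [SimulatedPair-class].
#' @export
simulatePair <- function(spec, truth = c("similar", "dissimilar"),
                         seed = spec@seed) {
  truth <- match.arg(truth)
  species <- names(spec@template@speciesProps)
  D <- length(species)
  nDA <- ceiling(spec@propDA * D)
  if (nDA < 1) stop("propDA * D must select at least one species")
  if (truth == "dissimilar" && 2 * nDA > D)
    stop("not enough species for disjoint differentially abundant sets")
  seed <- .resolveSeed(seed)
  seeds <- .deriveSeeds(seed, 3)  # design, ds1 counts, ds2 counts
  design <- .withSeed(seeds[1], function() {
    da1 <- sample(species, nDA)
    da2 <- if (truth == "similar") da1
           else sample(setdiff(species, da1), nDA)
    fc2 <- rnorm(nDA, spec@log2fcMean, spec@log2fcSd)
    nMask <- round((1 - spec@overlap) * D)
    masked <- if (nMask > 0) sample(species, nMask) else character(0)
    list(da1 = da1, da2 = da2, fc2 = setNames(fc2, da2), masked = masked)
  })
  fc1 <- setNames(rep(spec@log2fcMean, nDA), design$da1)
  ds1 <- simulateDataset(spec@template, spec@nPerGroup, fc1,
                         seed = seeds[2], sampleIdPrefix = "a")
  ds2 <- simulateDataset(spec@template, spec@nPerGroup, design$fc2,
                         seed = seeds[3], sampleIdPrefix = "b")
  if (length(design$masked)) {
    m <- counts(ds2)
    rn <- rownames(m)
    rn[rn %in% design$masked] <- paste0(rn[rn %in% design$masked], "xx")
    rownames(m) <- rn
    ds2 <- MicrobiomeCounts(m, groups = sampleGroups(ds2),
                            level = taxonLevel(ds2))
  }
  methods::new("SimulatedPair", ds1 = ds1, ds2 = ds2, truth = truth,
               daSpecies1 = design$da1, daSpecies2 = design$da2,
               log2fc1 = fc1, log2fc2 = design$fc2)
}

#' Measure sensitivity and specificity of the similarity call
#'
#' Simulates `spec@nPairs` dataset pairs (a `similarFraction` of them with
#' true similarity, the rest with disjoint differentially abundant sets),
#' runs [starmaps()] on each, and tabulates sensitivity and specificity of
#' the similarity call over a grid of omnibus-p thresholds (a pair is called
#' similar at threshold t when its omnibus p <= t). Fully seeded: pair i
#' uses a seed derived from `spec@seed`, so the evaluation is replayable
#' and independent of execution order.
#'
#' @param spec a [SimulationSpec-class].
#' @param similarFraction fraction of pairs with true similarity.
#' @param thresholds omnibus-p threshold grid (must include the operating
#'   point of interest, e.g. 0.05).
#' @param nPerm,nBoot,nDraws,nAxes,exact,refitBoot,exhaustive passed to
#'   [starmaps()].
#' @param nullLabels permute dataset 2's group labels before testing
#'   (destroys any group structure in ds2; used to measure the type-I error
#'   of the omnibus call).
#' @param verbose print a progress line every 25 pairs.
#' @return A [PerformanceSummary-class].
#' @export
evaluatePerformance <- function(spec, similarFraction = 0.5,
                                thresholds = seq(0, 1, by = 0.01),
                                nPerm = 10000, nBoot = 10000,
                                nDraws = 1000, nAxes = "all",
                                exact = FALSE, refitBoot = TRUE,
                                exhaustive = "auto", nullLabels = FALSE,
                                verbose = FALSE) {
  nPairs <- spec@nPairs
  if (nPairs < 2) stop("need at least 2 pairs")
  nSim <- round(nPairs * similarFraction)
  truth <- rep(c("similar", "dissimilar"), c(nSim, nPairs - nSim))
  pairSeeds <- .deriveSeeds(spec@seed, 2L * nPairs)
  res <- vector("list", nPairs)
  for (i in seq_len(nPairs)) {
    sp <- simulatePair(spec, truth[i], seed = pairSeeds[2 * i - 1])
    ds2 <- sp@ds2
    if (nullLabels) {
      g <- sampleGroups(ds2)
      g[] <- .withSeed(pairSeeds[2 * i], function() sample(g))
      ds2 <- MicrobiomeCounts(counts(ds2), groups = g,
                              level = taxonLevel(ds2))
    }
    r <- starmaps(sp@ds1, ds2, c("g1", "g2"), nPerm = nPerm, nBoot = nBoot,
                  nDraws = nDraws, nAxes = nAxes, seed = pairSeeds[2 * i],
                  exact = exact, refitBoot = refitBoot,
                  exhaustive = exhaustive)
    res[[i]] <- data.frame(pair = i, truth = truth[i],
                           omnibusP = omnibusP(r),
                           cosTheta = cosTheta(r),
                           seed = pairSeeds[2 * i])
    if (verbose && i %% 25 == 0)
      message("evaluated ", i, "/", nPairs, " pairs")
  }
  calls <- do.call(rbind, res)
  isSim <- calls$truth == "similar"
  sens <- vapply(thresholds, function(t)
    if (any(isSim)) mean(calls$omnibusP[isSim] <= t) else NA_real_,
    numeric(1))
  spcf <- vapply(thresholds, function(t)
    if (any(!isSim)) mean(calls$omnibusP[!isSim] > t) else NA_real_,
    numeric(1))
  if (!any(isSim) || !any(!isSim))
    message("single-class truth set: ROC undefined, reporting counts only")
  methods::new("PerformanceSummary", calls = calls,
               thresholds = thresholds, sensitivity = sens,
               specificity = spcf, nSimilar = sum(isSim),
               nDissimilar = sum(!isSim))
}
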