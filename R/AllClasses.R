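#' @import methods
#' @importFrom stats rnorm rlnorm rmultinom sd setNames var
#' @importFrom utils read.delim write.table
#' @importFrom graphics abline legend
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom Rcpp evalCpp
#' @useDynLib starmaps, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## MicrobiomeCounts: taxon-by-sample counts with group labels
## ---------------------------------------------------------------------------

#' Taxon-by-sample count table with group labels
#'
#' `MicrobiomeCounts` holds a non-negative integer taxon-by-sample count
#' matrix together with one group label per sample, the unit of input to the
#' similarity test. It extends
#' [SummarizedExperiment::SummarizedExperiment-class]; the counts live in the
#' `"counts"` assay, group labels in `colData(x)$group`, and an optional
#' taxonomic-rank label in `metadata(x)$level`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment-class]; no new
#'   slots are added.
#'
#' @seealso [MicrobiomeCounts()], [sampleGroups()], [matchTaxa()],
#'   [starmaps()]
#' @name MicrobiomeCounts-class
#' @exportClass MicrobiomeCounts
setClass("MicrobiomeCounts", contains = "SummarizedExperiment")

setValidity("MicrobiomeCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have taxon rownames and sample colnames")
  else {
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, "duplicate taxon identifiers")
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, "duplicate sample identifiers")
  }
  if (anyNA(m) || any(m < 0))
    msg <- c(msg, "counts must be non-negative and non-missing")
  else if (any(abs(m - round(m)) > 0))
    msg <- c(msg, "counts must be integral")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (anyNA(SummarizedExperiment::colData(object)$group))
    msg <- c(msg, "every sample needs a group label")
  if (length(msg)) msg else TRUE
})

#' Construct a MicrobiomeCounts object
#'
#' @param counts non-negative integer matrix, taxa in rows (rownames are the
#'   taxon identifiers), samples in columns (colnames are the sample
#'   identifiers).
#' @param groups group labels: either a character vector of length
#'   `ncol(counts)` (in column order) or a named vector/list keyed by sample
#'   identifier.
#' @param level optional taxonomic-rank label (e.g. `"species"`).
#' @return A [MicrobiomeCounts-class] object.
#' @examples
#' m <- matrix(rpois(12, 20), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
#' mc <- MicrobiomeCounts(m, groups = c("a", "a", "b", "b"))
#' sampleGroups(mc)
#' @export
MicrobiomeCounts <- function(counts, groups, level = NA_character_) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(counts), names(groups))
    if (length(missing))
      stop("samples missing group labels: ", paste(missing, collapse = ", "))
    groups <- unlist(groups)[colnames(counts)]
  } else if (length(groups) != ncol(counts)) {
    stop("'groups' must be named by sample or have one entry per sample")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(counts)),
    metadata = list(level = level))
  methods::new("MicrobiomeCounts", se)
}

## ---------------------------------------------------------------------------
## Compositions and ILR coordinates
## ---------------------------------------------------------------------------

#' Strictly positive relative-abundance table
#'
#' Per-sample compositions (columns summing to one, all entries strictly
#' positive), typically Dirichlet point estimates of relative abundance
#' produced by [dirichletPointEstimate()].
#'
#' @slot relAbund numeric matrix, taxa x samples; columns sum to 1 within
#'   1e-9 and every entry is > 0.
#' @seealso [dirichletPointEstimate()], [clrTransform()], [ilrTransform()]
#' @name CompositionTable-class
#' @exportClass CompositionTable
setClass("CompositionTable", representation(relAbund = "matrix"))

setValidity("CompositionTable", function(object) {
  m <- object@relAbund
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "relAbund needs taxon rownames and sample colnames")
  if (any(m <= 0)) msg <- c(msg, "all relative abundances must be > 0")
  if (any(abs(colSums(m) - 1) > 1e-9))
    msg <- c(msg, "columns must sum to 1 (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})

CompositionTable <- function(relAbund)
  methods::new("CompositionTable", relAbund = as.matrix(relAbund))

#' Isometric log-ratio coordinates
#'
#' Samples mapped into (D-1)-dimensional Euclidean space by the isometric
#' log-ratio (ILR) transform. Euclidean distances between rows of `coords`
#' equal Aitchison distances between the source compositions.
#'
#' @slot coords numeric matrix, samples x (D-1).
#' @slot basis D x (D-1) orthonormal contrast matrix; every column is
#'   orthogonal to the all-ones vector.
#' @seealso [ilrTransform()], [ilrBasis()]
#' @name IlrCoordinates-class
#' @exportClass IlrCoordinates
setClass("IlrCoordinates",
         representation(coords = "matrix", basis = "matrix"))

setValidity("IlrCoordinates", function(object) {
  V <- object@basis
  if (ncol(V) != nrow(V) - 1L)
    return("basis must be D x (D-1)")
  if (ncol(object@coords) != ncol(V))
    return("coords and basis disagree on dimension")
  if (max(abs(crossprod(V) - diag(ncol(V)))) > 1e-8)
    return("basis columns must be orthonormal")
  if (max(abs(colSums(V))) > 1e-8)
    return("basis columns must be orthogonal to the all-ones vector")
  TRUE
})

## ---------------------------------------------------------------------------
## PERMANOVA result
## ---------------------------------------------------------------------------

#' One-way PERMANOVA result
#'
#' @slot statistic observed pseudo-F (may be `Inf` when the within-group sum
#'   of squares is zero).
#' @slot pValue permutation p-value. In sampled mode the observed labelling
#'   is counted in both numerator and denominator, so
#'   `pValue >= 1/(nPerm+1)`; in exhaustive mode it is the exact fraction of
#'   all distinct labellings with pseudo-F >= observed.
#' @slot nPerm number of permutations used (distinct labellings in
#'   exhaustive mode).
#' @slot mode `"sampled"` or `"exhaustive"`.
#' @slot seed integer seed used in sampled mode (`NA` in exhaustive mode).
#' @seealso [permanova()], [pseudoF()]
#' @name PermanovaResult-class
#' @exportClass PermanovaResult
setClass("PermanovaResult",
         representation(statistic = "numeric", pValue = "numeric",
                        nPerm = "integer", mode = "character",
                        seed = "integer"))

## ---------------------------------------------------------------------------
## Matched pair and projection model
## ---------------------------------------------------------------------------

#' Two count tables aligned to their union taxon space
#'
#' @slot ds1,ds2 [MicrobiomeCounts-class] objects whose rows are the union
#'   taxa in a shared, deterministic order (ds1 order first, then taxa new to
#'   ds2 in ds2 order). Taxa absent from a dataset are zero-filled.
#' @slot unionTaxa character vector of the union taxon identifiers.
#' @slot presence factor per union taxon with levels
#'   `ds1_only`, `ds2_only`, `both`.
#' @seealso [matchTaxa()]
#' @name MatchedPair-class
#' @exportClass MatchedPair
setClass("MatchedPair",
         representation(ds1 = "MicrobiomeCounts", ds2 = "MicrobiomeCounts",
                        unionTaxa = "character", presence = "factor"))

setValidity("MatchedPair", function(object) {
  msg <- character()
  c1 <- counts(object@ds1); c2 <- counts(object@ds2)
  if (!identical(rownames(c1), object@unionTaxa) ||
      !identical(rownames(c2), object@unionTaxa))
    msg <- c(msg, "both tables must be aligned to unionTaxa")
  if (anyDuplicated(object@unionTaxa))
    msg <- c(msg, "unionTaxa must be unique")
  if (length(object@presence) != length(object@unionTaxa))
    msg <- c(msg, "presence must have one flag per union taxon")
  else {
    if (any(rowSums(c1)[object@presence == "ds2_only"] != 0))
      msg <- c(msg, "ds2_only taxa must be all-zero in ds1")
    if (any(rowSums(c2)[object@presence == "ds1_only"] != 0))
      msg <- c(msg, "ds1_only taxa must be all-zero in ds2")
  }
  if (length(msg)) msg else TRUE
})

#' PCA projection model fitted on the first dataset
#'
#' The affine map taking ILR coordinates to principal-component scores:
#' `scores = (ilr - center) %*% rotation`. Fitted on the first dataset only;
#' the identical map is applied to the second dataset.
#'
#' @slot center ILR-space mean vector of the first dataset.
#' @slot rotation orthonormal loading matrix, (D-1) x r.
#' @slot eigenvalues non-increasing PC variances (divisor n-1).
#' @slot basis the shared D x (D-1) ILR basis used for both datasets.
#' @seealso [fitProjection()], [projectSamples()]
#' @name ProjectionModel-class
#' @exportClass ProjectionModel
setClass("ProjectionModel",
         representation(center = "numeric", rotation = "matrix",
                        eigenvalues = "numeric", basis = "matrix"))

setValidity("ProjectionModel", function(object) {
  R <- object@rotation
  msg <- character()
  if (length(object@center) != nrow(R))
    msg <- c(msg, "center length must match rotation rows")
  if (max(abs(crossprod(R) - diag(ncol(R)))) > 1e-9)
    msg <- c(msg, "rotation columns must be orthonormal")
  ev <- object@eigenvalues
  if (length(ev) != ncol(R) || is.unsorted(rev(ev)) || any(ev < -1e-12))
    msg <- c(msg, "eigenvalues must be non-negative and non-increasing")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## StarmapsResult
## ---------------------------------------------------------------------------

#' Result of the cross-dataset similarity test
#'
#' @slot p1 PERMANOVA p-value for group segregation of dataset 1 on its own
#'   PC axes.
#' @slot p2Sample PERMANOVA p-value for dataset 2 segregation on dataset 1's
#'   axes (sample-label permutations).
#' @slot p2Taxon taxon-matching permutation p-value for dataset 2.
#' @slot p2 `max(p2Sample, p2Taxon)`.
#' @slot cosTheta cosine of the angle between the two group-difference
#'   directions in the shared PC space (`NA` if a direction is zero).
#' @slot p3 bootstrap p-value for the direction test.
#' @slot omnibusP intersection-union omnibus p, `max(p1, p2, p3)`.
#' @slot scores1,scores2 PC score matrices (samples x axes).
#' @slot nAxes number of PC axes used.
#' @slot settings list of all seeds, counts and options needed for replay.
#' @seealso [starmaps()]
#' @name StarmapsResult-class
#' @exportClass StarmapsResult
setClass("StarmapsResult",
         representation(p1 = "numeric", p2Sample = "numeric",
                        p2Taxon = "numeric", p2 = "numeric",
                        cosTheta = "numeric", p3 = "numeric",
                        omnibusP = "numeric", scores1 = "matrix",
                        scores2 = "matrix", nAxes = "integer",
                        settings = "list"))

setValidity("StarmapsResult", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@p2, max(object@p2Sample, object@p2Taxon))))
    msg <- c(msg, "p2 must equal max(p2Sample, p2Taxon)")
  if (!isTRUE(all.equal(object@omnibusP,
                        max(object@p1, object@p2, object@p3))))
    msg <- c(msg, "omnibusP must equal max(p1, p2, p3)")
  if (!is.na(object@cosTheta) && abs(object@cosTheta) > 1 + 1e-12)
    msg <- c(msg, "cosTheta must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulation types
## ---------------------------------------------------------------------------

#' Parametric species-abundance template for simulations
#'
#' A rank-abundance law over D species plus a sequencing-depth sampler,
#' emulating the uneven, heavy-tailed profile of fecal 16S surveys. Either
#' parametric (log-normal ranks, log-normal depths) from [makeTemplate()] or
#' empirical from a user count table via [templateFromCounts()].
#'
#' @slot speciesProps named strictly positive proportions summing to 1.
#' @slot depths list describing the depth sampler: either
#'   `list(type = "lognormal", meanlog, sdlog, min, max)` or
#'   `list(type = "empirical", depths)` (sampled with replacement).
#' @name Template-class
#' @exportClass Template
setClass("Template",
         representation(speciesProps = "numeric", depths = "list"))

setValidity("Template", function(object) {
  p <- object@speciesProps
  msg <- character()
  if (is.null(names(p)) || anyDuplicated(names(p)))
    msg <- c(msg, "speciesProps must have unique names")
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "speciesProps must be positive and sum to 1")
  if (!object@depths$type %in% c("lognormal", "empirical"))
    msg <- c(msg, "unknown depth sampler type")
  if (length(msg)) msg else TRUE
})

#' Specification of one simulation condition
#'
#' @slot nPerGroup samples per group in each simulated dataset (N).
#' @slot log2fcMean mean base-2 log fold change applied to differentially
#'   abundant species (constant in dataset 1).
#' @slot log2fcSd standard deviation s of the per-species log2 fold change
#'   applied to dataset 2.
#' @slot overlap proportion of species whose names are shared between the
#'   two datasets (the remainder are masked so they cannot be matched).
#' @slot propDA proportion of species that are differentially abundant.
#' @slot nPairs number of dataset pairs for a performance evaluation.
#' @slot template [Template-class] to draw counts from.
#' @slot seed master seed.
#' @seealso [SimulationSpec()], [simulatePair()], [evaluatePerformance()]
#' @name SimulationSpec-class
#' @exportClass SimulationSpec
setClass("SimulationSpec",
         representation(nPerGroup = "integer", log2fcMean = "numeric",
                        log2fcSd = "numeric", overlap = "numeric",
                        propDA = "numeric", nPairs = "integer",
                        template = "Template", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@overlap <= 0 || object@overlap > 1)
    msg <- c(msg, "overlap must be in (0, 1]")
  if (object@propDA <= 0 || object@propDA >= 1)
    msg <- c(msg, "propDA must be in (0, 1)")
  if (object@log2fcSd < 0) msg <- c(msg, "log2fcSd must be >= 0")
  D <- length(object@template@speciesProps)
  if (ceiling(object@propDA * D) < 1)
    msg <- c(msg, "propDA * D must select at least one species")
  if (length(msg)) msg else TRUE
})

#' A simulated dataset pair with known truth
#'
#' @slot ds1,ds2 simulated [MicrobiomeCounts-class] tables (groups `g1`,
#'   `g2`).
#' @slot truth `"similar"` or `"dissimilar"`.
#' @slot daSpecies1,daSpecies2 identifiers of the differentially abundant
#'   species in each dataset (pre-masking names).
#' @slot log2fc1,log2fc2 named per-species log2 fold changes applied.
#' @name SimulatedPair-class
#' @exportClass SimulatedPair
setClass("SimulatedPair",
         representation(ds1 = "MicrobiomeCounts", ds2 = "MicrobiomeCounts",
                        truth = "character", daSpecies1 = "character",
                        daSpecies2 = "character", log2fc1 = "numeric",
                        log2fc2 = "numeric"))

setValidity("SimulatedPair", function(object) {
  msg <- character()
  if (!object@truth %in% c("similar", "dissimilar"))
    msg <- c(msg, "truth must be 'similar' or 'dissimilar'")
  if (object@truth == "similar" &&
      !setequal(object@daSpecies1, object@daSpecies2))
    msg <- c(msg, "similar pairs must share the differentially abundant set")
  if (object@truth == "dissimilar" &&
      (length(intersect(object@daSpecies1, object@daSpecies2)) > 0 ||
       length(object@daSpecies1) != length(object@daSpecies2)))
    msg <- c(msg, "dissimilar pairs need disjoint, equal-sized sets")
  if (length(msg)) msg else TRUE
})

#' Sensitivity/specificity summary over simulated pairs
#'
#' @slot calls data.frame with one row per simulated pair: `pair`, `truth`,
#'   `omnibusP`, `cosTheta`, `seed`.
#' @slot thresholds omnibus-p threshold grid.
#' @slot sensitivity,specificity rates per threshold (a pair is called
#'   similar when `omnibusP <= threshold`).
#' @slot nSimilar,nDissimilar truth counts.
#' @seealso [evaluatePerformance()], [rocPoints()]
#' @name PerformanceSummary-class
#' @exportClass PerformanceSummary
setClass("PerformanceSummary",
         representation(calls = "data.frame", thresholds = "numeric",
                        sensitivity = "numeric", specificity = "numeric",
                        nSimilar = "integer", nDissimilar = "integer"))
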