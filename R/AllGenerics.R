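## Generics and simple accessors. Heavier computational methods live in the
## module files (compositions.R, permanova.R, starmaps.R, simulate.R, io.R).

#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata
NULL

#' Extract the count matrix
#'
#' @param object a [MicrobiomeCounts-class] object.
#' @param ... ignored.
#' @return taxon-by-sample numeric matrix of counts.
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname counts
#' @export
setMethod("counts", "MicrobiomeCounts",
          function(object, ...) assay(object, "counts"))

#' Group label per sample
#'
#' @param object a [MicrobiomeCounts-class] object.
#' @return named character vector, sample id -> group.
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "MicrobiomeCounts", function(object)
  setNames(as.character(colData(object)$group), colnames(object)))

#' Taxonomic-rank label of a count table
#'
#' @param object a [MicrobiomeCounts-class] object.
#' @return rank label (possibly `NA`).
#' @export
setGeneric("taxonLevel", function(object) standardGeneric("taxonLevel"))

#' @rdname taxonLevel
#' @export
setMethod("taxonLevel", "MicrobiomeCounts",
          function(object) metadata(object)$level)

#' Relative-abundance matrix of a composition table
#'
#' @param object a [CompositionTable-class] object.
#' @return taxon-by-sample matrix of strictly positive proportions.
#' @export
setGeneric("relAbund", function(object) standardGeneric("relAbund"))

#' @rdname relAbund
#' @export
setMethod("relAbund", "CompositionTable", function(object) object@relAbund)

#' ILR coordinates and basis
#'
#' @param object an [IlrCoordinates-class] object.
#' @return `ilrCoords()`: samples x (D-1) coordinate matrix; `ilrBasisOf()`:
#'   the D x (D-1) contrast matrix that produced it.
#' @export
setGeneric("ilrCoords", function(object) standardGeneric("ilrCoords"))

#' @rdname ilrCoords
#' @export
setMethod("ilrCoords", "IlrCoordinates", function(object) object@coords)

#' @rdname ilrCoords
#' @export
setGeneric("ilrBasisOf", function(object) standardGeneric("ilrBasisOf"))

#' @rdname ilrCoords
#' @export
setMethod("ilrBasisOf", "IlrCoordinates", function(object) object@basis)

#' Permutation p-value of a test result
#'
#' @param object a [PermanovaResult-class] object.
#' @return the p-value.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "PermanovaResult", function(object) object@pValue)

#' Pseudo-F statistic
#'
#' With a coordinate matrix and labels, computes the one-way PERMANOVA
#' pseudo-F (see [permanova()]); on a [PermanovaResult-class] it extracts the
#' observed statistic.
#'
#' @param x samples-by-k coordinate matrix, or a [PermanovaResult-class].
#' @param ... passed on (`labels` for the matrix method).
#' @return the pseudo-F value.
#' @export
setGeneric("pseudoF", function(x, ...) standardGeneric("pseudoF"))

#' @rdname pseudoF
#' @export
setMethod("pseudoF", "PermanovaResult", function(x, ...) x@statistic)

#' Component and omnibus p-values of a similarity test
#'
#' @param object a [StarmapsResult-class] object.
#' @return `componentP()`: named vector `p1`, `p2_sample`, `p2_taxon`, `p2`,
#'   `p3`; `omnibusP()`: the intersection-union omnibus p (their maximum).
#' @export
setGeneric("omnibusP", function(object) standardGeneric("omnibusP"))

#' @rdname omnibusP
#' @export
setMethod("omnibusP", "StarmapsResult", function(object) object@omnibusP)

#' @rdname omnibusP
#' @export
setGeneric("componentP", function(object) standardGeneric("componentP"))

#' @rdname omnibusP
#' @export
setMethod("componentP", "StarmapsResult", function(object)
  c(p1 = object@p1, p2_sample = object@p2Sample, p2_taxon = object@p2Taxon,
    p2 = object@p2, p3 = object@p3))

#' Cosine of the angle between group-difference directions
#'
#' For two numeric vectors, the standard cosine similarity; on a
#' [StarmapsResult-class], the observed value for the compared group pair.
#' A value of 1 means the two datasets change in the same direction, -1 the
#' opposite direction, 0 perpendicular (not comparable).
#'
#' @param x numeric direction vector or a [StarmapsResult-class].
#' @param y second direction vector (vector method only).
#' @return cosine in `[-1, 1]`; `NA` if either vector has zero length.
#' @examples
#' cosTheta(c(1, 0), c(0, 1))  # 0
#' cosTheta(c(1, 1), c(-1, -1))  # -1
#' @export
setGeneric("cosTheta", function(x, y) standardGeneric("cosTheta"))

#' @rdname cosTheta
#' @export
setMethod("cosTheta", c("numeric", "numeric"), function(x, y) {
  if (length(x) != length(y))
    stop("direction vectors must have equal length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  max(-1, min(1, sum(x * y) / (nx * ny)))
})

#' @rdname cosTheta
#' @export
setMethod("cosTheta", c("StarmapsResult", "missing"),
          function(x, y) x@cosTheta)

#' PC scores of a similarity test
#'
#' @param object a [StarmapsResult-class] object.
#' @param which `"ds1"` or `"ds2"`.
#' @return samples-by-axes score matrix.
#' @export
setGeneric("scores", function(object, which = "ds1") standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "StarmapsResult", function(object, which = "ds1") {
  which <- match.arg(which, c("ds1", "ds2"))
  if (which == "ds1") object@scores1 else object@scores2
})

#' ROC points of a performance evaluation
#'
#' @param object a [PerformanceSummary-class] object.
#' @return data.frame with `threshold`, `fpr` (1 - specificity) and `tpr`
#'   (sensitivity), ordered by increasing false-positive rate.
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

#' @rdname rocPoints
#' @export
setMethod("rocPoints", "PerformanceSummary", function(object) {
  d <- data.frame(threshold = object@thresholds,
                  fpr = 1 - object@specificity,
                  tpr = object@sensitivity)
  d[order(d$fpr, d$tpr), , drop = FALSE]
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "MicrobiomeCounts", function(object) {
  g <- table(sampleGroups(object))
  cat("MicrobiomeCounts:", nrow(object), "taxa x", ncol(object), "samples",
      if (!is.na(taxonLevel(object))) paste0("(", taxonLevel(object), ")"),
      "\n  groups:",
      paste(sprintf("%s (n=%d)", names(g), as.integer(g)), collapse = ", "),
      "\n")
})

setMethod("show", "CompositionTable", function(object) {
  cat("CompositionTable:", nrow(object@relAbund), "taxa x",
      ncol(object@relAbund), "samples, strictly positive\n")
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PERMANOVA (one-way): pseudo-F = %.4g, p = %.4g (%s, %d %s)\n",
              object@statistic, object@pValue, object@mode, object@nPerm,
              if (object@mode == "exhaustive") "distinct labellings"
              else "permutations"))
})

setMethod("show", "MatchedPair", function(object) {
  cat("MatchedPair:", length(object@unionTaxa), "union taxa (",
      sum(object@presence == "both"), "shared,",
      sum(object@presence == "ds1_only"), "ds1-only,",
      sum(object@presence == "ds2_only"), "ds2-only )\n")
  if (sum(object@presence == "both") == 0L)
    cat("  note: the two datasets share no taxa\n")
})

setMethod("show", "ProjectionModel", function(object) {
  cat("ProjectionModel:", ncol(object@rotation), "axes in",
      nrow(object@rotation), "ILR dimensions; eigenvalues",
      paste(signif(utils::head(object@eigenvalues, 3), 3), collapse = ", "),
      if (length(object@eigenvalues) > 3) "...", "\n")
})

setMethod("show", "StarmapsResult", function(object) {
  cat("Cross-dataset similarity test (intersection-union omnibus)\n")
  cat(sprintf("  p1 (ds1 segregation)        : %.4g\n", object@p1))
  cat(sprintf("  p2 (ds2 segregation)        : %.4g  [sample %.4g, taxon %.4g]\n",
              object@p2, object@p2Sample, object@p2Taxon))
  cat(sprintf("  p3 (direction, cos theta = %.3f): %.4g\n",
              object@cosTheta, object@p3))
  cat(sprintf("  omnibus p                   : %.4g  (%d PC axes)\n",
              object@omnibusP, object@nAxes))
})

setMethod("show", "Template", function(object) {
  cat("Template:", length(object@speciesProps), "species;",
      "top share", signif(max(object@speciesProps), 3), ";",
      object@depths$type, "depth sampler\n")
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec: N=%d/group, log2FC=%g (s=%g), overlap=%g, propDA=%g, %d pairs, seed=%d\n",
    object@nPerGroup, object@log2fcMean, object@log2fcSd, object@overlap,
    object@propDA, object@nPairs, object@seed))
})

setMethod("show", "SimulatedPair", function(object) {
  cat("SimulatedPair (truth:", object@truth, ")\n  ds1: ")
  methods::show(object@ds1)
  cat("  ds2: ")
  methods::show(object@ds2)
})

setMethod("show", "PerformanceSummary", function(object) {
  i <- which.min(abs(object@thresholds - 0.05))
  cat("PerformanceSummary:", object@nSimilar, "similar +",
      object@nDissimilar, "dissimilar pairs\n")
  cat(sprintf("  at omnibus p <= %.3g: sensitivity %.3f, specificity %.3f\n",
              object@thresholds[i], object@sensitivity[i],
              object@specificity[i]))
})
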