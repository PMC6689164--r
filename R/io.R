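## Readers, writers and bundled example data. Count tables are UTF-8
## tab-separated text: first header cell "taxon_id", one column per sample,
## integer cells, no quoting (so taxonomy strings containing semicolons
## round-trip unchanged). Metadata is a two-column TSV (sample_id, group).

#' Read a taxon-by-sample count table with sample metadata
#'
#' @param path count table: TSV with first column `taxon_id` and one integer
#'   column per sample, or a BIOM file (requires the `biomformat` package).
#' @param metadata path to a TSV with columns `sample_id` and `group`.
#'   Every sample in the count table must have a group label.
#' @param format `"tsv"` or `"biom"`.
#' @param level optional taxonomic-rank label to record.
#' @return A [MicrobiomeCounts-class]. Taxa with zero total count are
#'   retained (taxon matching may still use them).
#' @export
readCountTable <- function(path, metadata, format = c("tsv", "biom"),
                           level = NA_character_) {
  format <- match.arg(format)
  if (format == "tsv") {
    header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    if (header[1] != "taxon_id")
      stop("first header cell must be 'taxon_id', found '", header[1], "'")
    sampleIds <- header[-1]
    dup <- unique(sampleIds[duplicated(sampleIds)])
    if (length(dup))
      stop("duplicated sample column(s): ", paste(dup, collapse = ", "))
    d <- read.delim(path, check.names = FALSE, colClasses = "character",
                    quote = "")
    taxa <- d[[1]]
    dupT <- unique(taxa[duplicated(taxa)])
    if (length(dupT))
      stop("duplicated taxon identifier(s): ", paste(dupT, collapse = ", "))
    m <- as.matrix(d[, -1, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
    bad <- is.na(num) | abs(num - round(num)) > 0
    if (any(bad))
      stop("non-integer cell(s), e.g. taxon '",
           taxa[which(bad, arr.ind = TRUE)[1, 1]], "'")
    dimnames(num) <- list(taxa, sampleIds)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    num <- as.matrix(biomformat::biom_data(b))
    if (any(num < 0) || any(abs(num - round(num)) > 0))
      stop("BIOM matrix must hold non-negative integers")
  }
  meta <- read.delim(metadata, check.names = FALSE, quote = "",
                     colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(meta)))
    stop("metadata must have columns 'sample_id' and 'group'")
  groups <- setNames(meta$group, meta$sample_id)
  missing <- setdiff(colnames(num), names(groups))
  if (length(missing))
    stop("samples missing group labels: ", paste(missing, collapse = ", "))
  MicrobiomeCounts(num, groups = groups[colnames(num)], level = level)
}

#' Write a count table (and optionally its metadata) as TSV
#'
#' @param x a [MicrobiomeCounts-class].
#' @param path output TSV path.
#' @param metadataPath optional path for a companion `sample_id`/`group`
#'   TSV.
#' @return invisibly, `path`.
#' @export
writeCountTable <- function(x, path, metadataPath = NULL) {
  m <- counts(x)
  d <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath)) {
    g <- sampleGroups(x)
    write.table(data.frame(sample_id = names(g), group = unname(g)),
                metadataPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a taxonomy table
#'
#' @param path TSV with columns `taxon_id` and `taxonomy`
#'   (semicolon-delimited lineage, outermost rank first).
#' @return named character vector, taxon id -> lineage string.
#' @export
readTaxonomy <- function(path) {
  d <- read.delim(path, check.names = FALSE, quote = "",
                  colClasses = "character")
  if (!all(c("taxon_id", "taxonomy") %in% colnames(d)))
    stop("taxonomy file must have columns 'taxon_id' and 'taxonomy'")
  setNames(d$taxonomy, d$taxon_id)
}

## ---- result serialization -------------------------------------------------

.resultAsList <- function(x) {
  list(schema = "starmaps-result/1",
       p1 = x@p1, p2_sample = x@p2Sample, p2_taxon = x@p2Taxon, p2 = x@p2,
       cos_theta = x@cosTheta, p3 = x@p3, omnibus_p = x@omnibusP,
       n_axes = x@nAxes,
       scores1 = as.data.frame(x@scores1),
       scores2 = as.data.frame(x@scores2),
       settings = x@settings)
}

#' Serialize results to JSON or TSV
#'
#' JSON is lossless (all p-values at full precision, scores, seeds and
#' settings; schema-versioned). TSV is a flat one-row summary for a
#' [StarmapsResult-class] (columns `p1`, `p2_sample`, `p2_taxon`, `p2`,
#' `cos_theta`, `p3`, `omnibus_p`, `n_axes`, `seed`) or the per-threshold
#' table for a [PerformanceSummary-class].
#'
#' @param x a [StarmapsResult-class] or [PerformanceSummary-class].
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return invisibly, `path`.
#' @seealso [readStarmapsResult()]
#' @export
setGeneric("writeResult",
           function(x, path, format = c("json", "tsv"))
             standardGeneric("writeResult"))

#' @rdname writeResult
#' @export
setMethod("writeResult", "StarmapsResult",
          function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(.resultAsList(x), path, auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE, na = "null")
  } else {
    d <- data.frame(p1 = x@p1, p2_sample = x@p2Sample,
                    p2_taxon = x@p2Taxon, p2 = x@p2,
                    cos_theta = x@cosTheta, p3 = x@p3,
                    omnibus_p = x@omnibusP, n_axes = x@nAxes,
                    seed = x@settings$seed)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
})

#' @rdname writeResult
#' @export
setMethod("writeResult", "PerformanceSummary",
          function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(schema = "starmaps-performance/1",
           n_similar = x@nSimilar, n_dissimilar = x@nDissimilar,
           thresholds = x@thresholds, sensitivity = x@sensitivity,
           specificity = x@specificity, calls = x@calls),
      path, auto_unbox = TRUE, digits = I(17), pretty = TRUE, na = "null")
  } else {
    write.table(data.frame(threshold = x@thresholds,
                           sensitivity = x@sensitivity,
                           specificity = x@specificity),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
})

#' Read back a JSON-serialized similarity-test result
#'
#' Restores a [StarmapsResult-class] written by [writeResult()] with
#' `format = "json"`; p-values round-trip bit-exactly.
#'
#' @param path JSON file path.
#' @return A [StarmapsResult-class].
#' @export
readStarmapsResult <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, "starmaps-result/1"))
    stop("not a serialized similarity-test result: ", path)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  methods::new("StarmapsResult",
               p1 = num(j$p1), p2Sample = num(j$p2_sample),
               p2Taxon = num(j$p2_taxon), p2 = num(j$p2),
               cosTheta = num(j$cos_theta), p3 = num(j$p3),
               omnibusP = num(j$omnibus_p),
               scores1 = as.matrix(j$scores1),
               scores2 = as.matrix(j$scores2),
               nAxes = as.integer(j$n_axes), settings = j$settings)
}

## ---- bundled example ------------------------------------------------------

#' Small deterministic example dataset pair
#'
#' A tiny bundled pair for documentation and smoke tests: two datasets of 2
#' groups x 4 samples over a 30-species template, simulated with a strong
#' shared effect (log2 fold change 4 on 10% of species, full overlap), so
#' their group differences are truly similar. Regenerated deterministically
#' from a fixed seed.
#'
#' @param seed fixed seed of the bundled pair (change to get a different
#'   example).
#' @return list with elements `ds1`, `ds2` ([MicrobiomeCounts-class]) and
#'   `truth`.
#' @export
exampleCountPair <- function(seed = 20260901) {
  spec <- SimulationSpec(nPerGroup = 4, log2fcMean = 4, log2fcSd = 0,
                         overlap = 1, propDA = 0.10, nPairs = 2,
                         template = makeTemplate(D = 30, seed = seed),
                         seed = seed)
  sp <- simulatePair(spec, "similar", seed = seed)
  list(ds1 = sp@ds1, ds2 = sp@ds2, truth = sp@truth)
}

## ---- basic plots ----------------------------------------------------------

#' Plot an ROC curve of a performance evaluation
#'
#' @param x a [PerformanceSummary-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data.frame of ROC points.
#' @export
plotRoc <- function(x, ...) {
  d <- rocPoints(x)
  graphics::plot(d$fpr, d$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false-positive fraction (1 - specificity)",
                 ylab = "true-positive fraction (sensitivity)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  i <- which.min(abs(x@thresholds - 0.05))
  graphics::points(1 - x@specificity[i], x@sensitivity[i], pch = 19)
  invisible(d)
}

#' Scatter the first two PC axes of both datasets
#'
#' @param result a [StarmapsResult-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotScores <- function(result, ...) {
  s1 <- scores(result, "ds1"); s2 <- scores(result, "ds2")
  if (ncol(s1) < 2) stop("need at least two PC axes to plot")
  xl <- range(s1[, 1], s2[, 1]); yl <- range(s1[, 2], s2[, 2])
  graphics::plot(s1[, 1], s1[, 2], pch = 19, xlim = xl, ylim = yl,
                 xlab = "PC1", ylab = "PC2", ...)
  graphics::points(s2[, 1], s2[, 2], pch = 1)
  graphics::legend("topright", pch = c(19, 1), bty = "n",
                   legend = c("dataset 1", "dataset 2 (projected)"))
  invisible(NULL)
}
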