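## Compositional preprocessing: sparse counts -> strictly positive
## compositions -> Euclidean (ILR) coordinates.

#' Dirichlet point estimate of relative abundance
#'
#' Replaces a sparse count table by strictly positive per-sample relative
#' abundances. For each sample the estimate is the mean of `nDraws` Monte
#' Carlo draws from a Dirichlet distribution whose parameter vector is the
#' sample's counts plus `offset`; this is the only zero handling applied
#' anywhere in the pipeline. With `exact = TRUE` the closed-form Dirichlet
#' mean `(c_i + offset) / sum(c_j + offset)` is returned instead (the limit
#' of the Monte Carlo mean as `nDraws` grows).
#'
#' Draws are made per sample, independently across samples, in column order,
#' under a single seed, so the estimate for a whole table is reproducible.
#'
#' @param x a [MicrobiomeCounts-class] object or a non-negative count matrix
#'   (taxa x samples, dimnames required).
#' @param nDraws number of Monte Carlo Dirichlet instances per sample.
#' @param offset pseudo-count added to every cell of the Dirichlet parameter.
#' @param seed integer seed for the Monte Carlo draws (ignored when
#'   `exact = TRUE`); `NULL` draws one.
#' @param exact use the closed-form Dirichlet mean instead of Monte Carlo.
#' @return A [CompositionTable-class]; columns sum to 1 and all entries are
#'   strictly positive.
#' @examples
#' m <- matrix(c(3, 1, 0, 5), nrow = 2,
#'             dimnames = list(c("tA", "tB"), c("s1", "s2")))
#' relAbund(dirichletPointEstimate(m, exact = TRUE))  # s1: 0.7, 0.3
#' @export
dirichletPointEstimate <- function(x, nDraws = 1000, offset = 0.5,
                                   seed = NULL, exact = FALSE) {
  m <- if (methods::is(x, "MicrobiomeCounts")) counts(x) else as.matrix(x)
  if (length(m) == 0L) stop("empty count table")
  if (anyNA(m) || any(m < 0)) stop("counts must be non-negative")
  if (nDraws < 1) stop("nDraws must be >= 1")
  if (offset <= 0) stop("offset must be > 0")
  a <- m + offset
  if (exact) {
    est <- sweep(a, 2, colSums(a), "/")
  } else {
    seed <- .resolveSeed(seed)
    est <- .withSeed(seed, function()
      .dirichletMcMean(a, 0, as.integer(nDraws)))
    dimnames(est) <- dimnames(m)
    ## guard against numerically zero means from extreme underflow
    if (any(est <= 0)) {
      est[est <= 0] <- .Machine$double.xmin
      est <- sweep(est, 2, colSums(est), "/")
    }
  }
  CompositionTable(est)
}

#' Centered log-ratio transform
#'
#' Maps each sample's composition to the log scale, centering by the sample's
#' mean log: `clr(x)_i = log(x_i) - mean(log(x))`. Rows of the result sum to
#' zero. Used internally as the oracle for the ILR isometry and by the
#' taxon-permutation null.
#'
#' @param comp a [CompositionTable-class] or strictly positive taxa x samples
#'   matrix.
#' @return samples x D matrix of CLR coordinates (samples in rows).
#' @examples
#' clrTransform(matrix(c(0.8, 0.2), 2, 1,
#'                     dimnames = list(c("a", "b"), "s1")))
#' @export
clrTransform <- function(comp) {
  m <- if (methods::is(comp, "CompositionTable")) relAbund(comp)
       else as.matrix(comp)
  if (any(m <= 0)) stop("compositions must be strictly positive")
  lg <- t(log(m))                       # samples x D
  lg - rowMeans(lg)
}

#' Default ILR contrast basis
#'
#' A fixed Helmert-type sequential-binary-partition basis: balance j
#' contrasts the geometric mean of the first j taxa against taxon j+1, taxa
#' taken in locale-independent sorted identifier order. Columns are
#' orthonormal and orthogonal to the all-ones vector. Because the whole
#' pipeline is invariant to the choice of orthonormal log-ratio basis, the
#' particular partition is immaterial; it is fixed so results are
#' deterministic given the taxon identifiers.
#'
#' @param taxa character vector of taxon identifiers (or a single integer D
#'   for an unnamed basis).
#' @return D x (D-1) contrast matrix with rownames `taxa`.
#' @export
ilrBasis <- function(taxa) {
  if (is.numeric(taxa) && length(taxa) == 1L) {
    D <- as.integer(taxa)
    ord <- seq_len(D)
    nm <- NULL
  } else {
    D <- length(taxa)
    ord <- .stableOrder(taxa)
    nm <- taxa
  }
  if (D < 2L) stop("need at least two taxa")
  V <- matrix(0, D, D - 1L)
  for (j in seq_len(D - 1L)) {
    V[seq_len(j), j] <- sqrt(1 / (j * (j + 1)))
    V[j + 1L, j] <- -sqrt(j / (j + 1))
  }
  out <- matrix(0, D, D - 1L)
  out[ord, ] <- V                        # row i of out corresponds to taxa[i]
  rownames(out) <- nm
  out
}

#' Isometric log-ratio transform
#'
#' Maps strictly positive compositions into (D-1)-dimensional Euclidean
#' space: `ilr = clr %*% basis`. The map is an isometry of the Aitchison
#' geometry, so Euclidean distances between ILR rows equal Aitchison
#' distances between the source compositions.
#'
#' @param comp a [CompositionTable-class] or strictly positive taxa x samples
#'   matrix.
#' @param basis optional D x (D-1) contrast matrix satisfying the
#'   [IlrCoordinates-class] invariants; default [ilrBasis()] on the taxon
#'   identifiers.
#' @return An [IlrCoordinates-class] object carrying the coordinates and the
#'   basis used.
#' @examples
#' comp <- matrix(c(0.8, 0.2), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' ilrCoords(ilrTransform(comp))  # (1/sqrt(2)) * log(0.8/0.2) ~ 0.9803
#' @export
ilrTransform <- function(comp, basis = NULL) {
  m <- if (methods::is(comp, "CompositionTable")) relAbund(comp)
       else as.matrix(comp)
  if (any(m <= 0)) stop("compositions must be strictly positive")
  if (is.null(basis)) basis <- ilrBasis(rownames(m))
  basis <- as.matrix(basis)
  if (nrow(basis) != nrow(m))
    stop("basis has ", nrow(basis), " rows but composition has ",
         nrow(m), " taxa")
  if (ncol(basis) != nrow(basis) - 1L ||
      max(abs(crossprod(basis) - diag(ncol(basis)))) > 1e-8 ||
      max(abs(colSums(basis))) > 1e-8)
    stop("basis must be an orthonormal D x (D-1) log-ratio contrast matrix")
  cl <- clrTransform(m)
  methods::new("IlrCoordinates", coords = cl %*% basis, basis = basis)
}

#' Aggregate counts to a higher taxonomic rank
#'
#' Sums counts over all taxa sharing the lineage prefix down to `level`.
#' Lineage strings are `delim`-separated ranks in descending order
#' (e.g. `"Bacteria;Firmicutes;Bacilli"`). Taxa whose lineage is shallower
#' than the requested rank are pooled into an
#' `"unclassified (<deepest known prefix>)"` bucket. Per-sample totals are
#' preserved exactly.
#'
#' @param x a [MicrobiomeCounts-class] object.
#' @param taxonomy named character vector, taxon id -> lineage string; every
#'   taxon of `x` must be present.
#' @param level target rank: a rank name from `ranks` or a 1-based depth.
#' @param ranks rank names corresponding to lineage depth, outermost first.
#' @param delim lineage delimiter.
#' @return A [MicrobiomeCounts-class] at the requested level; row names are
#'   the truncated lineage strings.
#' @export
aggregateToLevel <- function(x, taxonomy, level,
                             ranks = c("kingdom", "phylum", "class",
                                       "order", "family", "genus",
                                       "species"),
                             delim = ";") {
  if (is.character(level)) {
    depth <- match(level, ranks)
    if (is.na(depth)) stop("unknown rank label: ", level)
  } else depth <- as.integer(level)
  if (depth < 1L) stop("level depth must be >= 1")
  m <- counts(x)
  missing <- setdiff(rownames(m), names(taxonomy))
  if (length(missing))
    stop("taxa without taxonomy: ", paste(missing, collapse = ", "))
  lin <- strsplit(as.character(taxonomy[rownames(m)]), delim, fixed = TRUE)
  key <- vapply(lin, function(p) {
    p <- trimws(p)
    if (length(p) >= depth)
      paste(p[seq_len(depth)], collapse = delim)
    else
      paste0("unclassified (", paste(p, collapse = delim), ")")
  }, character(1))
  agg <- rowsum(m, group = key, reorder = FALSE)
  lev <- if (is.character(level)) level else paste0("depth", depth)
  MicrobiomeCounts(agg, groups = sampleGroups(x), level = lev)
}
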