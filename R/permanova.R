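## One-way permutational multivariate ANOVA on Euclidean coordinates: the
## segregation engine behind every component of the similarity test.

## ---- internals ------------------------------------------------------------

## F statistic pieces from coordinates. Uses the centroid identity: for
## Euclidean distances, the distance-based between/within sums of squares
## equal the classical coordinate-based ones.
.fPieces <- function(coords, labels) {
  coords <- as.matrix(coords)
  f <- factor(labels)
  n <- nrow(coords); a <- nlevels(f)
  center <- colMeans(coords)
  sst <- sum(sweep(coords, 2, center)^2)
  ssb <- 0
  for (lv in levels(f)) {
    idx <- which(f == lv)
    mg <- colMeans(coords[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * sum((mg - center)^2)
  }
  ssw <- max(sst - ssb, 0)
  list(n = n, a = a, ssb = ssb, ssw = ssw)
}

.fFromPieces <- function(p) {
  msb <- p$ssb / (p$a - 1)
  msw <- p$ssw / (p$n - p$a)
  if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
}

## Vectorized pseudo-F for many labellings at once. A is an integer matrix
## (one labelling per row, values 1..a); group sizes are constant across rows
## because every row is a permutation of the same label multiset.
.fMany <- function(coords, A, sizes) {
  coords <- as.matrix(coords)
  n <- nrow(coords); a <- length(sizes)
  center <- colMeans(coords)
  sst <- sum(sweep(coords, 2, center)^2)
  tot <- colSums(coords)
  ssb <- -sum(tot^2) / n
  for (g in seq_len(a)) {
    Sg <- (A == g) %*% coords            # per-labelling group sums
    ssb <- ssb + rowSums(Sg^2) / sizes[g]
  }
  ssb <- pmax(ssb, 0)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (a - 1)
  msw <- ssw / (n - a)
  ifelse(msw == 0, ifelse(msb == 0, 0, Inf), msb / msw)
}

## Number of distinct assignments of the label multiset to positions.
.nAssignments <- function(sizes) {
  v <- exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
  round(v)
}

## Enumerate every distinct labelling exactly once (groups distinguishable).
## Returns an integer matrix, one labelling per row.
.enumAssignments <- function(sizes) {
  n <- sum(sizes)
  out <- matrix(NA_integer_, nrow = .nAssignments(sizes), ncol = n)
  row <- 0L
  ## the last group is filled implicitly by enumerating all but it
  rec2 <- function(avail, g, partial) {
    if (g == length(sizes)) {
      partial[avail] <- g
      row <<- row + 1L
      out[row, ] <<- partial
      return(invisible())
    }
    picks <- utils::combn(length(avail), sizes[g])
    for (k in seq_len(ncol(picks))) {
      sel <- avail[picks[, k]]
      p2 <- partial
      p2[sel] <- g
      rec2(setdiff(avail, sel), g + 1L, p2)
    }
  }
  rec2(seq_len(n), 1L, integer(n))
  out
}

## Tolerant >= comparison so floating-point noise cannot drop the observed
## (or a genuinely tied) labelling from the null count. Conservative.
.countGE <- function(fs, fObs) {
  if (!is.finite(fObs)) return(sum(fs >= fObs))
  sum(fs >= fObs - 1e-9 * max(1, abs(fObs)))
}

## ---- exported operations --------------------------------------------------

#' @describeIn pseudoF one-way pseudo-F from a samples-by-k Euclidean
#'   coordinate matrix and group labels:
#'   `F = (SS_between/(a-1)) / (SS_within/(n-a))`. Returns `Inf` when the
#'   within-group sum of squares is zero but groups differ.
#' @param labels group labels, one per row of `x`.
#' @export
setMethod("pseudoF", "matrix", function(x, labels, ...) {
  f <- factor(labels)
  if (nlevels(f) < 2L) stop("need at least two groups")
  if (any(table(f) < 1L)) stop("every group needs at least one sample")
  if (nrow(x) != length(f)) stop("one label per coordinate row required")
  if (nrow(x) <= nlevels(f)) stop("need more samples than groups")
  .fFromPieces(.fPieces(x, f))
})

#' One-way PERMANOVA on Euclidean coordinates
#'
#' Tests group segregation of multivariate samples by permuting group labels
#' and comparing the one-way pseudo-F of each labelling with the observed
#' one. Distances are Euclidean on the supplied coordinates (here, ILR or
#' principal-component space), where the distance-based and coordinate-based
#' sums of squares coincide.
#'
#' When the number of distinct labellings is at most `nPerm` (and
#' `exhaustive = "auto"`, the default) every distinct labelling is evaluated
#' exactly once and the p-value is the exact enumeration fraction; otherwise
#' `nPerm` labellings are sampled with replacement and the observed one is
#' counted in both numerator and denominator. Labellings whose pseudo-F ties
#' the observed value count toward the p-value.
#'
#' @param coords samples-by-k numeric matrix.
#' @param labels group label per row; at least two groups.
#' @param nPerm number of sampled permutations (also the enumeration cutoff
#'   for the automatic exhaustive mode).
#' @param seed seed for sampled permutations (`NULL` draws one).
#' @param exhaustive `"auto"`, `"always"` or `"never"`.
#' @return A [PermanovaResult-class] object.
#' @examples
#' co <- matrix(c(0, 2, 10, 12), ncol = 1)
#' r <- permanova(co, c("A", "A", "B", "B"))
#' pseudoF(r)   # 50: SSB = 100, SSW = 4
#' pValue(r)    # 1/6: exhaustive over the 6 distinct labellings
#' @export
permanova <- function(coords, labels, nPerm = 10000, seed = NULL,
                      exhaustive = c("auto", "always", "never")) {
  exhaustive <- match.arg(exhaustive)
  if (nPerm < 1) stop("nPerm must be >= 1")
  coords <- as.matrix(coords)
  f <- factor(labels)
  fObs <- pseudoF(coords, f)
  sizes <- as.integer(table(f))
  nAssign <- .nAssignments(sizes)
  doExh <- exhaustive == "always" ||
    (exhaustive == "auto" && nAssign <= nPerm)
  if (doExh) {
    A <- .enumAssignments(sizes)
    ## map enumeration's group g to the g-th factor level's size: sizes are
    ## already in level order, matching as.integer(f)
    fs <- .fMany(coords, A, sizes)
    p <- .countGE(fs, fObs) / nAssign
    methods::new("PermanovaResult", statistic = fObs, pValue = p,
                 nPerm = as.integer(nAssign), mode = "exhaustive",
                 seed = NA_integer_)
  } else {
    seed <- .resolveSeed(seed)
    count <- .withSeed(seed, function()
      .samplePermCount(coords, as.integer(f), as.numeric(sizes),
                       as.integer(nPerm), fObs))
    p <- (1 + count) / (nPerm + 1)
    methods::new("PermanovaResult", statistic = fObs, pValue = p,
                 nPerm = as.integer(nPerm), mode = "sampled", seed = seed)
  }
}
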