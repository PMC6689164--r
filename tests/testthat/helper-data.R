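## Shared fixtures, all built in code.

## tiny deterministic count table: D taxa x (2 * nPer) samples, two groups
tinyCounts <- function(D = 5, nPer = 2, seed = 42, lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(D * 2 * nPer, lambda), nrow = D,
              dimnames = list(sprintf("t%02d", seq_len(D)),
                              sprintf("s%02d", seq_len(2 * nPer))))
  MicrobiomeCounts(m, groups = rep(c("A", "B"), each = nPer))
}

## strongly separated two-group dataset from the simulation machinery
separatedCounts <- function(N = 6, D = 100, log2fc = 4, seed = 99) {
  tpl <- makeTemplate(D = D, seed = seed)
  da <- names(tpl@speciesProps)[seq_len(ceiling(0.1 * D))]
  simulateDataset(tpl, N, setNames(rep(log2fc, length(da)), da),
                  seed = seed + 1)
}

## random strictly positive composition matrix (taxa x samples)
randomComposition <- function(D = 8, n = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rgamma(D * n, shape = 2), nrow = D,
              dimnames = list(sprintf("t%02d", seq_len(D)),
                              sprintf("s%02d", seq_len(n))))
  sweep(m, 2, colSums(m), "/")
}

## random orthogonal rotation of an ILR basis (still a valid basis)
rotatedBasis <- function(basis, seed = 7) {
  set.seed(seed)
  k <- ncol(basis)
  Q <- qr.Q(qr(matrix(rnorm(k * k), k)))
  basis %*% Q
}
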