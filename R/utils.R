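## Internal helpers shared across modules.

## Resolve a user-supplied seed: NULL draws one (and reports it in results),
## anything else is coerced to a 32-bit integer.
.resolveSeed <- function(seed) {
  if (is.null(seed))
    seed <- sample.int(.Machine$integer.max - 1L, 1L)
  as.integer(seed)
}

## Derive n child seeds from one parent seed without disturbing the caller's
## RNG stream. Deterministic: same parent, same children.
.deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## Run fn() under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

## Locale-independent, deterministic ordering of identifier strings.
.stableOrder <- function(x) order(x, method = "radix")

## Subset a MicrobiomeCounts to the samples of the named groups, preserving
## column order; errors if a group is absent.
.subsetGroups <- function(x, groupPair) {
  g <- sampleGroups(x)
  missing <- setdiff(groupPair, unique(g))
  if (length(missing))
    stop("group(s) not present: ", paste(missing, collapse = ", "))
  x[, g %in% groupPair]
}
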