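test_that("taxon matching builds the union space deterministically", {
  m1 <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  m2 <- matrix(1:6, 3, 2, dimnames = list(c("B", "C", "D"), c("u1", "u2")))
  d1 <- MicrobiomeCounts(m1, groups = c("x", "y"))
  d2 <- MicrobiomeCounts(m2, groups = c("x", "y"))
  pr <- matchTaxa(d1, d2)
  expect_identical(pr@unionTaxa, c("A", "B", "C", "D"))
  expect_equal(unname(counts(pr@ds1)["D", ]), c(0, 0))
  expect_equal(unname(counts(pr@ds2)["A", ]), c(0, 0))
  expect_identical(as.character(pr@presence),
                   c("ds1_only", "both", "both", "ds2_only"))
  ## original counts preserved
  expect_equal(counts(pr@ds1)[rownames(m1), ], m1)
  expect_equal(counts(pr@ds2)[rownames(m2), ], m2)

  ## identical taxon sets: identity, all flags "both"
  prSame <- matchTaxa(d1, d1)
  expect_true(all(prSame@presence == "both"))
  expect_equal(counts(prSame@ds2), m1)

  ## disjoint sets: all rows half zero, with a message
  m3 <- matrix(1:8, 4, 2, dimnames = list(paste0("z", 1:4), c("v1", "v2")))
  d3 <- MicrobiomeCounts(m3, groups = c("x", "y"))
  expect_message(prDis <- matchTaxa(d1, d3), "share no taxa")
  expect_identical(length(prDis@unionTaxa), 7L)
  expect_equal(sum(counts(prDis@ds1)[paste0("z", 1:4), ]), 0)
})

test_that("PCA projection reproduces ds1 geometry and variance", {
  ds1 <- tinyCounts(D = 12, nPer = 4, seed = 3)
  pr <- matchTaxa(ds1, ds1)
  model <- fitProjection(pr, exact = TRUE)
  s1 <- projectSamples(model, pr, "ds1", exact = TRUE)
  s2 <- projectSamples(model, pr, "ds2", exact = TRUE)
  expect_equal(s1, s2, tolerance = 1e-12)

  ## total score variance equals total ILR variance
  comp <- dirichletPointEstimate(counts(pr@ds1), exact = TRUE)
  ilr <- ilrCoords(ilrTransform(comp, model@basis))
  expect_equal(sum(apply(s1, 2, var)), sum(apply(ilr, 2, var)),
               tolerance = 1e-6)

  ## score covariance is diagonal with the eigenvalues
  cv <- cov(s1)
  expect_equal(diag(cv), model@eigenvalues, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-9)
  expect_true(all(diff(model@eigenvalues) <= 1e-12))

  ## duplicating every sample keeps directions, scales eigenvalues by the
  ## n-1 divisor ratio 2(n-1)/(2n-1)
  mdup <- cbind(counts(ds1), counts(ds1))
  colnames(mdup) <- sprintf("d%02d", seq_len(ncol(mdup)))
  dsDup <- MicrobiomeCounts(mdup, groups = unname(rep(sampleGroups(ds1), 2)))
  mDup <- fitProjection(matchTaxa(dsDup, dsDup), exact = TRUE)
  n <- ncol(counts(ds1))
  expect_equal(mDup@eigenvalues,
               model@eigenvalues * 2 * (n - 1) / (2 * n - 1),
               tolerance = 1e-9)
  expect_equal(abs(crossprod(mDup@rotation, model@rotation)),
               diag(ncol(model@rotation)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("group directions and cosine follow their definitions", {
  sc <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0))
  g <- c("A", "A", "B", "B")
  expect_equal(groupDirection(sc, g, c("A", "B")), c(1, 0))
  expect_equal(groupDirection(sc, g, c("B", "A")), c(-1, 0))
  sc1 <- rbind(c(0, 1), c(3, 5))
  expect_equal(groupDirection(sc1, c("A", "B"), c("A", "B")), c(3, 4))
  expect_error(groupDirection(sc, g, c("A", "Z")), "unknown group")

  expect_equal(cosTheta(c(1, 2), c(1, 2)), 1)
  expect_equal(cosTheta(c(1, 2), -c(1, 2)), -1)
  expect_equal(cosTheta(c(1, 0), c(0, 1)), 0)
  expect_true(is.na(cosTheta(c(0, 0), c(1, 0))))
})

test_that("self-comparison yields cosine exactly 1 and a consistent omnibus", {
  ds1 <- separatedCounts(N = 4, D = 40, seed = 17)
  res <- starmaps(ds1, ds1, c("g1", "g2"), nPerm = 300, nBoot = 300,
                  nDraws = 300, seed = 5)
  expect_identical(cosTheta(res), 1)
  p <- componentP(res)
  expect_identical(omnibusP(res), max(p[["p1"]], p[["p2"]], p[["p3"]]))
  expect_identical(p[["p2"]], max(p[["p2_sample"]], p[["p2_taxon"]]))
  ## identical scores: the two sample-permutation tests agree exactly
  ## (both exhaustive at n = 8)
  expect_identical(p[["p1"]], p[["p2_sample"]])
  expect_identical(scores(res, "ds1"), scores(res, "ds2"))
  ## exhaustive support at 4 + 4: multiples of 1/70
  expect_equal(p[["p1"]] * 70, round(p[["p1"]] * 70), tolerance = 1e-9)
})

test_that("label-swapped self-comparison flips the direction sign", {
  ds1 <- separatedCounts(N = 4, D = 40, seed = 23)
  g <- sampleGroups(ds1)
  swapped <- MicrobiomeCounts(counts(ds1),
                              groups = ifelse(g == "g1", "g2", "g1"))
  res <- starmaps(ds1, swapped, c("g1", "g2"), nPerm = 200, nBoot = 200,
                  nDraws = 200, seed = 6)
  expect_identical(cosTheta(res), -1)
  expect_lt(componentP(res)[["p3"]], 0.05)
})

test_that("a zero group-difference direction gives p3 = 1", {
  ds1 <- separatedCounts(N = 3, D = 20, seed = 31)
  ## ds2 whose two groups are identical point sets: direction exactly 0
  ## in exact mode
  m <- counts(tinyCounts(D = 20, nPer = 3, seed = 8))
  rownames(m) <- rownames(counts(ds1))
  m[, 4:6] <- m[, 1:3]
  ds2 <- MicrobiomeCounts(m, groups = rep(c("g1", "g2"), each = 3))
  expect_message(
    res <- starmaps(ds1, ds2, c("g1", "g2"), nPerm = 100, nBoot = 100,
                    exact = TRUE, seed = 9),
    "zero length")
  expect_true(is.na(cosTheta(res)))
  expect_identical(componentP(res)[["p3"]], 1)
  expect_identical(omnibusP(res), 1)
})

test_that("the taxon-matching null guards against generic structure", {
  ## dissimilar pairs with strong but disjoint effects: the sample
  ## permutation test alone is fooled, the taxon-matching test is not
  spec <- SimulationSpec(nPerGroup = 6, log2fcMean = 4, log2fcSd = 0,
                         overlap = 1, nPairs = 2, seed = 301)
  p2t <- vapply(1:8, function(i) {
    sp <- simulatePair(spec, "dissimilar", seed = 400 + i)
    r <- starmaps(sp@ds1, sp@ds2, c("g1", "g2"), nPerm = 300, nBoot = 50,
                  nDraws = 300, seed = 500 + i)
    componentP(r)[["p2_taxon"]]
  }, numeric(1))
  expect_gte(median(p2t), 0.05)
})

test_that("results carry full replay settings", {
  pair <- exampleCountPair()
  res <- starmaps(pair$ds1, pair$ds2, c("g1", "g2"), nPerm = 100,
                  nBoot = 100, nDraws = 100, seed = 12)
  st <- res@settings
  expect_identical(st$seed, 12L)
  expect_true(all(c("seedDirichlet", "seedP1", "seedP2Sample",
                    "seedP2Taxon", "seedBoot") %in% names(st)))
  expect_identical(st$nUnionTaxa, 30L)
  expect_identical(st$groupPair1, c("g1", "g2"))
  expect_identical(res@nAxes, ncol(scores(res, "ds1")))
})
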