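test_that("parametric templates are deterministic rank-abundance laws", {
  t1 <- makeTemplate(D = 100, seed = 5)
  t2 <- makeTemplate(D = 100, seed = 5)
  expect_identical(t1@speciesProps, t2@speciesProps)
  p <- t1@speciesProps
  expect_length(p, 100)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(diff(unname(p)) <= 0))   # non-increasing after sorting
  expect_error(makeTemplate(D = 5), ">= 10")
  expect_error(makeTemplate(depthMedian = 10), "invalid")

  d <- starmaps:::.drawDepths(t1, 500)
  expect_true(all(d >= 1000 & d <= 1e6))
  expect_true(all(d == round(d)))
})

test_that("empirical templates reuse observed abundances and depths", {
  x <- tinyCounts(D = 12, nPer = 3, seed = 4)
  tpl <- templateFromCounts(x)
  expect_equal(sum(tpl@speciesProps), 1, tolerance = 1e-12)
  expect_identical(tpl@depths$type, "empirical")
  expect_setequal(starmaps:::.drawDepths(tpl, 50),
                  as.integer(colSums(counts(x))))
})

test_that("fold changes are applied by renormalized multiplication", {
  ## one species at 0.5 with log2fc = 1: 2*0.5 / (2*0.5 + 0.5) = 2/3
  p <- c(a = 0.5, b = 0.5)
  expect_equal(starmaps:::.effectProps(p, c(a = 1)),
               c(a = 2 / 3, b = 1 / 3), tolerance = 1e-12)
  ## zero effect is the identity
  expect_identical(starmaps:::.effectProps(p, c(a = 0)), p)
  expect_error(starmaps:::.effectProps(p, c(zz = 1)), "not in template")
})

test_that("simulated datasets have multinomial structure and groups", {
  tpl <- makeTemplate(D = 50, seed = 9)
  da <- names(tpl@speciesProps)[1:5]
  ds <- simulateDataset(tpl, N = 4, setNames(rep(2, 5), da), seed = 21)
  m <- counts(ds)
  expect_identical(dim(m), c(50L, 8L))
  expect_true(all(m == round(m)) && all(m >= 0))
  ## column sums are the drawn depths: within the truncation bounds
  expect_true(all(colSums(m) >= 1000 & colSums(m) <= 1e6))
  expect_identical(as.integer(table(sampleGroups(ds))), c(4L, 4L))
  ## determinism
  ds2 <- simulateDataset(tpl, N = 4, setNames(rep(2, 5), da), seed = 21)
  expect_identical(counts(ds), counts(ds2))
})

test_that("pair construction encodes the similarity truth", {
  spec <- SimulationSpec(nPerGroup = 3, log2fcMean = 2, log2fcSd = 1,
                         overlap = 1, nPairs = 2,
                         template = makeTemplate(D = 60, seed = 2),
                         seed = 10)
  sim <- simulatePair(spec, "similar", seed = 30)
  expect_identical(sort(sim@daSpecies1), sort(sim@daSpecies2))
  expect_identical(unname(sim@log2fc1),
                   rep(2, ceiling(0.1 * 60)))
  dis <- simulatePair(spec, "dissimilar", seed = 30)
  expect_length(intersect(dis@daSpecies1, dis@daSpecies2), 0)
  expect_identical(length(dis@daSpecies1), length(dis@daSpecies2))
  ## per-species ds2 effects vary when s > 0
  expect_gt(sd(sim@log2fc2), 0)
  ## determinism
  sim2 <- simulatePair(spec, "similar", seed = 30)
  expect_identical(counts(sim@ds2), counts(sim2@ds2))
})

test_that("overlap masking hides exactly the requested species fraction", {
  spec <- SimulationSpec(nPerGroup = 3, log2fcMean = 2, log2fcSd = 1,
                         overlap = 0.5, nPairs = 2,
                         template = makeTemplate(D = 100, seed = 3),
                         seed = 11)
  sp <- simulatePair(spec, "similar", seed = 12)
  masked <- grepl("xx$", rownames(counts(sp@ds2)))
  expect_identical(sum(masked), 50L)
  pr <- matchTaxa(sp@ds1, sp@ds2)
  expect_identical(sum(pr@presence == "ds2_only"), 50L)
  expect_identical(sum(pr@presence == "ds1_only"), 50L)
})

test_that("performance summaries have coherent ROC endpoints", {
  spec <- SimulationSpec(nPerGroup = 3, log2fcMean = 4, log2fcSd = 0,
                         overlap = 1, nPairs = 4,
                         template = makeTemplate(D = 40, seed = 6),
                         seed = 13)
  perf <- evaluatePerformance(spec, thresholds = c(0, 0.05, 0.5, 1),
                              nPerm = 100, nBoot = 100, nDraws = 100)
  expect_identical(perf@nSimilar, 2L)
  expect_identical(perf@nDissimilar, 2L)
  ## threshold 1 calls everything, threshold 0 calls nothing
  expect_identical(perf@sensitivity[4], 1)
  expect_identical(perf@specificity[4], 0)
  expect_identical(perf@sensitivity[1], 0)
  expect_identical(perf@specificity[1], 1)
  roc <- rocPoints(perf)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  ## determinism of the whole evaluation
  perf2 <- evaluatePerformance(spec, thresholds = c(0, 0.05, 0.5, 1),
                               nPerm = 100, nBoot = 100, nDraws = 100)
  expect_identical(perf@calls, perf2@calls)
})
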