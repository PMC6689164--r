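test_that("Dirichlet point estimate matches the closed form and is symmetric", {
  ## all-zero counts: Dirichlet(0.5, 0.5, 0.5) is symmetric around 1/3
  m0 <- matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  est <- relAbund(dirichletPointEstimate(m0, nDraws = 1000, seed = 4))
  expect_true(all(abs(est - 1 / 3) < 0.02))

  ## closed-form mean for counts (3, 1): (3.5, 1.5) / 5
  m <- matrix(c(3, 1), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(relAbund(dirichletPointEstimate(m, exact = TRUE))[, 1],
               c(a = 0.7, b = 0.3), tolerance = 1e-12)

  ## Monte Carlo mean converges to the closed form
  mc <- relAbund(dirichletPointEstimate(m, nDraws = 1e5, seed = 11))[, 1]
  expect_true(all(abs(mc - c(0.7, 0.3)) < 0.005))

  expect_error(dirichletPointEstimate(matrix(numeric(0), 0, 0)), "empty")
  expect_error(dirichletPointEstimate(matrix(-1, 1, 1,
    dimnames = list("a", "s")), exact = TRUE), "non-negative")
})

test_that("Dirichlet estimates are closed compositions for any counts", {
  for (s in 1:20) {
    set.seed(s)
    D <- sample(3:25, 1); n <- sample(2:4, 1)
    m <- matrix(rpois(D * n, sample(c(0.5, 5, 200), 1)), nrow = D,
                dimnames = list(sprintf("t%d", 1:D), sprintf("s%d", 1:n)))
    est <- relAbund(dirichletPointEstimate(m, nDraws = 300, seed = s))
    expect_true(all(est > 0))
    expect_true(max(abs(colSums(est) - 1)) < 1e-9)
  }
})

test_that("CLR rows are log-ratios centered to zero", {
  comp <- matrix(c(0.8, 0.2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(drop(clrTransform(comp)), c(a = log(2), b = -log(2)),
               tolerance = 1e-12)
  unif <- matrix(1 / 4, 4, 2,
                 dimnames = list(letters[1:4], c("s1", "s2")))
  expect_true(all(abs(clrTransform(unif)) < 1e-12))
  rc <- randomComposition(D = 9, n = 6, seed = 2)
  expect_true(max(abs(rowSums(clrTransform(rc)))) < 1e-9)
  expect_error(clrTransform(matrix(c(0, 1), 2, 1,
    dimnames = list(c("a", "b"), "s"))), "positive")
})

test_that("ILR is an isometry with an orthonormal default basis", {
  rc <- randomComposition(D = 12, n = 8, seed = 5)
  V <- ilrBasis(rownames(rc))
  expect_equal(crossprod(V), diag(11), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(max(abs(colSums(V))) < 1e-12)

  ilr <- ilrTransform(rc)
  expect_equal(as.matrix(dist(ilrCoords(ilr))),
               as.matrix(dist(clrTransform(rc))), tolerance = 1e-9)

  ## two-part balance closed form
  two <- matrix(c(0.8, 0.2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(drop(ilrCoords(ilrTransform(two))),
               log(0.8 / 0.2) / sqrt(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(drop(ilrCoords(ilrTransform(two))), 0.9803,
               tolerance = 1e-4, ignore_attr = TRUE)

  ## identity element maps to the origin
  unif <- matrix(1 / 5, 5, 1, dimnames = list(letters[1:5], "s1"))
  expect_true(all(abs(ilrCoords(ilrTransform(unif))) < 1e-12))

  ## any valid basis gives coordinates differing by a rotation only
  V2 <- rotatedBasis(V, seed = 8)
  ilr2 <- ilrTransform(rc, V2)
  expect_equal(as.matrix(dist(ilrCoords(ilr2))),
               as.matrix(dist(ilrCoords(ilr))), tolerance = 1e-9)

  expect_error(ilrTransform(rc, V[1:5, ]), "rows")
  expect_error(ilrTransform(rc, V * 2), "orthonormal")
})

test_that("rank aggregation preserves per-sample totals exactly", {
  m <- matrix(c(1, 2, 3,
                4, 5, 6), nrow = 3,
              dimnames = list(c("sp1", "sp2", "sp3"), c("s1", "s2")))
  x <- MicrobiomeCounts(m, groups = c("A", "B"))
  tax <- c(sp1 = "Bact;Firm;GenA", sp2 = "Bact;Firm;GenA",
           sp3 = "Bact;Firm;GenB")
  g <- aggregateToLevel(x, tax, "phylum")
  expect_equal(nrow(counts(g)), 1L)
  expect_equal(unname(colSums(counts(g))), unname(colSums(m)))

  gen <- aggregateToLevel(x, tax, 3)
  expect_equal(nrow(counts(gen)), 2L)
  expect_equal(unname(colSums(counts(gen))), unname(colSums(m)))
  expect_equal(unname(counts(gen)["Bact;Firm;GenA", ]),
               unname(m["sp1", ] + m["sp2", ]))

  ## four taxa, one phylum, one sample
  m4 <- matrix(1:4, 4, 1, dimnames = list(paste0("x", 1:4), "s1"))
  x4 <- MicrobiomeCounts(m4, groups = c(s1 = "A"))
  tax4 <- setNames(rep("Bact;Firm", 4), rownames(m4))
  expect_equal(unname(counts(aggregateToLevel(x4, tax4, "phylum"))[1, 1]),
               10)

  ## shallow lineages fall into an unclassified bucket
  tax[["sp3"]] <- "Bact"
  cl <- aggregateToLevel(x, tax, "class", ranks = c("kingdom", "phylum",
                                                    "class"))
  expect_true("unclassified (Bact)" %in% rownames(counts(cl)))
  expect_equal(unname(colSums(counts(cl))), unname(colSums(m)))

  expect_error(aggregateToLevel(x, tax, "strain"), "unknown rank")
})
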