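test_that("pseudo-F matches hand computation and degenerate cases", {
  co <- matrix(c(0, 2, 10, 12), ncol = 1)
  lab <- c("A", "A", "B", "B")
  ## SS_between = 100, SS_within = 4, F = (100/1)/(4/2) = 50
  expect_equal(pseudoF(co, lab), 50, tolerance = 1e-9)

  ## identical group point sets with scatter: SS_between = 0
  co0 <- matrix(c(0, 1, 0, 1), ncol = 1)
  expect_equal(pseudoF(co0, lab), 0)

  ## zero within-group scatter but separated groups: +Inf flag
  coInf <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(pseudoF(coInf, lab), Inf)

  expect_error(pseudoF(co, c("A", "A", "A", "A")), "two groups")
  expect_error(pseudoF(matrix(0, 3, 1), c("A", "B", "C")), "more samples")
})

test_that("pseudo-F is invariant under rigid motions and label swaps", {
  set.seed(10)
  co <- matrix(rnorm(16), ncol = 2)
  lab <- rep(c("A", "B"), each = 4)
  f0 <- pseudoF(co, lab)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(pseudoF(co %*% R + 5, lab), f0, tolerance = 1e-9)
  lab2 <- ifelse(lab == "A", "B", "A")
  expect_equal(pseudoF(co, lab2), f0, tolerance = 1e-12)
  r1 <- permanova(co, lab, exhaustive = "always")
  r2 <- permanova(co, lab2, exhaustive = "always")
  expect_identical(pValue(r1), pValue(r2))
})

test_that("exhaustive enumeration gives exact permutation p-values", {
  co <- matrix(c(0, 2, 10, 12), ncol = 1)
  lab <- c("A", "A", "B", "B")
  r <- permanova(co, lab)
  expect_identical(r@mode, "exhaustive")
  expect_identical(r@nPerm, 6L)          # choose(4, 2) labellings
  ## with equal group sizes the complementary labelling always ties the
  ## observed pseudo-F (swapping group names leaves F unchanged), so the
  ## exact enumeration p is 2/6 even though the partition is uniquely best
  expect_equal(pValue(r), 2 / 6)

  ## all samples identical: every labelling ties, p = 1
  rTie <- permanova(matrix(1, 4, 2), lab)
  expect_equal(pValue(rTie), 1)

  ## sampled mode keeps the conservative observed-included convention
  rs <- permanova(co, lab, nPerm = 200, seed = 4, exhaustive = "never")
  expect_identical(rs@mode, "sampled")
  expect_gte(pValue(rs), 1 / 201)
  expect_lt(abs(pValue(rs) - 2 / 6),
            3 * sqrt(2 / 6 * 4 / 6 / 200) + 0.01)
})

test_that("sampled p-values converge to the exhaustive enumeration", {
  set.seed(21)
  for (nPer in c(2, 3)) {
    co <- matrix(rnorm(2 * nPer * 2, mean = rep(c(0, 1.2),
                                                each = nPer)), ncol = 2)
    lab <- rep(c("A", "B"), each = nPer)
    pEx <- pValue(permanova(co, lab, exhaustive = "always"))
    pSa <- pValue(permanova(co, lab, nPerm = 10000, seed = 33,
                            exhaustive = "never"))
    expect_lt(abs(pSa - pEx), 3 * sqrt(pEx * (1 - pEx) / 10000) + 1e-3)
  }
})

test_that("pseudo-F and p agree with the vegan adonis oracle", {
  skip_if_not_installed("vegan")
  set.seed(14)
  co <- matrix(rnorm(20 * 3, mean = rep(c(0, 0.8), each = 10)), ncol = 3)
  lab <- factor(rep(c("A", "B"), each = 10))
  ours <- permanova(co, lab, nPerm = 5000, seed = 5, exhaustive = "never")
  ad <- vegan::adonis2(dist(co) ~ lab, permutations = 5000)
  expect_equal(pseudoF(ours), ad$F[1], tolerance = 1e-9)
  pv <- ad$`Pr(>F)`[1]
  expect_lt(abs(pValue(ours) - pv),
            3 * sqrt(pv * (1 - pv) / 5000) + 2e-3)
})

test_that("type-I error is at the nominal level under random labels", {
  ## 5 + 4 samples (unequal sizes avoid complement ties): exhaustive p is
  ## uniform on k/126, so P(p < 0.05) = 6/126 ~ 0.048
  set.seed(77)
  lab <- rep(c("A", "B"), c(5, 4))
  rej <- vapply(seq_len(2000), function(i) {
    co <- matrix(rnorm(18), ncol = 2)
    pValue(permanova(co, lab)) < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
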