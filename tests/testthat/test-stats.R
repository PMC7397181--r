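test_that("Mood's median test matches the exact enumeration oracle", {
  # worked example: fully separated triples -> Fisher two-sided p = 0.1
  r <- moodsMedianTest(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  # identical samples
  r2 <- moodsMedianTest(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(r2$p_value, 0.9)
  # all values tie at the grand median
  expect_warning(r3 <- moodsMedianTest(rep(2, 4), rep(2, 4)), "tie")
  expect_equal(r3$p_value, 1)
  # random small samples vs enumeration oracle (Fisher's-exact regime)
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(sample(4:7, 1))
    y <- rnorm(sample(4:7, 1), mean = runif(1, -1, 1))
    expect_equal(moodsMedianTest(x, y)$p_value, oracleMoodsP(x, y),
                 tolerance = 0.01)
  }
})

test_that("Welch t-test reports two-sided significance and direction", {
  r <- welchTTest(c(-0.3, -0.4), c(0.3, 0.4))
  expect_equal(r$estimate2 - r$estimate1, 0.7)
  expect_lt(r$p_value, 0.05)
  expect_equal(r$direction, "y_greater")
  expect_equal(welchTTest(c(1, 2, 3), c(3, 2, 1))$p_value, 1)
  expect_error(welchTTest(1, c(1, 2)), "at least 2")
})

test_that("exact binomial matches closed forms and enumeration", {
  r <- binomialTest(10, 10, 0.5)
  expect_equal(r$p_value, 2 / 1024, tolerance = 1e-12)
  # two-sided by summing point probabilities <= observed
  r2 <- binomialTest(30, 40, 0.5)
  d <- dbinom(0:40, 40, 0.5)
  expect_equal(r2$p_value, sum(d[d <= d[31] + 1e-12]), tolerance = 1e-9)
  expect_error(binomialTest(5, 4), "invalid")
})

test_that("hypergeometric enrichment matches the closed form", {
  r <- hypergeomEnrichment(5, 5, 5, 20)
  expect_equal(r$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # upper tail sums at-least-k terms
  r2 <- hypergeomEnrichment(3, 10, 8, 30)
  manual <- sum(dhyper(3:8, 8, 22, 10))
  expect_equal(r2$p_value, manual, tolerance = 1e-12)
})

test_that("BH correction matches the hand step-up computation", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.005, 0.04, 0.2, 0.9)
  expect_equal(bhFDR(p), c(0.02, 0.08, 0.8 / 3, 0.9))
  # order preserved, q >= p, monotone in sorted order
  set.seed(1)
  p <- runif(20)
  q <- bhFDR(p)
  expect_true(all(q >= p))
  expect_true(!is.unsorted(q[order(p)]))
})

test_that("gene-set enrichment flags the planted set under BH FDR", {
  sets <- list(hit = sprintf("g%d", 1:20),
               miss = sprintf("g%d", 81:100))
  universe <- sprintf("g%d", 1:100)
  res <- geneSetEnrichment(sprintf("g%d", 1:15), sets, universe, fdr = 0.001)
  expect_true(res$significant[res$set == "hit"])
  expect_false(res$significant[res$set == "miss"])
})

test_that("GMT files parse into named gene sets", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), f)
  gs <- readGMT(f)
  expect_equal(names(gs), c("setA", "setB"))
  expect_equal(gs$setA, c("g1", "g2", "g3"))
})
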