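test_that("indicator PWMs hit exactly their consensus occurrences", {
  pw <- makeTestPWMs()
  hits <- scanPWM(pw$M1, paste0(strrep("A", 10), "GCAUGC", strrep("A", 5)))
  expect_equal(hits$position, 11L)
  # reversed consensus with no chance match gives no hits
  none <- scanPWM(pw$M1, paste0(strrep("A", 10), "CGUACG"))
  expect_equal(nrow(none), 0L)
  # sequence shorter than the motif
  expect_equal(nrow(scanPWM(pw$M1, "ACG")), 0L)
})

test_that("the exact score-distribution DP matches 4^k enumeration", {
  set.seed(61)
  for (r in 1:5) {
    k <- sample(4:6, 1)
    m <- matrix(stats::rgamma(4 * k, 1), 4, k,
                dimnames = list(c("A", "C", "G", "U"), NULL))
    m <- sweep(m, 2, colSums(m), "/")
    for (q in c(0.9, 0.95, 0.99)) {
      lo <- SpliceLoc:::.pwmLogOdds(m)
      dist <- SpliceLoc:::.pwmScoreDistribution(lo)
      upper <- rev(cumsum(rev(dist$prob)))
      ok <- which(upper <= 1 - q)
      thr <- if (length(ok)) dist$score[min(ok)] else Inf
      expect_equal(thr, oraclePwmThreshold(m, q), tolerance = 1e-6)
    }
  }
})

test_that("planted motifs are recovered by permutation enrichment", {
  pw <- makeTestPWMs()
  set.seed(62)
  mkseq <- function(n, plant = NULL) {
    vapply(seq_len(n), function(i) {
      x <- sample(c("A", "C", "G", "U"), 200, replace = TRUE)
      if (!is.null(plant)) {
        off <- sample(50:150, 1)
        x[off:(off + nchar(plant) - 1)] <- strsplit(plant, "")[[1]]
      }
      paste(x, collapse = "")
    }, character(1))
  }
  nuc <- mkseq(25, "GCAUGC")    # M1 consensus in every nuclear intron
  bg <- mkseq(25)
  r <- rbpEnrichment(pw, nuc, bg, n_shuffles = 200, seed = 1,
                     threshold_quantile = 0.99)
  expect_lt(r$q_value[r$feature_id == "M1"], 0.05)
  expect_gt(r$ratio[r$feature_id == "M1"], 1)
  # identical sets: ratios 1, nothing significant
  r2 <- rbpEnrichment(pw, nuc, nuc, n_shuffles = 100, seed = 1)
  expect_equal(r2$ratio, rep(1, 8))
  expect_true(all(r2$q_value > 0.5))
})

test_that("motif densities are invariant to background duplication", {
  pw <- makeTestPWMs()[c("M1", "M4")]
  set.seed(63)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "U"), 300, replace = TRUE),
          collapse = ""), character(1))
  r1 <- rbpEnrichment(pw, seqs, seqs, n_shuffles = 10, seed = 1)
  r2 <- rbpEnrichment(pw, seqs, rep(seqs, 2), n_shuffles = 10, seed = 1)
  expect_equal(r1$density_background, r2$density_background,
               tolerance = 1e-9)
})

test_that("consistency report applies the cross-dataset fraction rule", {
  mk <- function(q1, q2, rat) data.frame(
    feature_id = c("M1", "M2"), ratio = c(rat, 0.5),
    q_value = c(q1, q2))
  tabs <- list(mk(0.001, 0.5, 3), mk(0.001, 0.5, 3), mk(0.001, 0.001, 3),
               mk(0.2, 0.001, 3), mk(0.001, 0.001, 3))
  rep <- consistencyReport(tabs, min_frac = 0.8, alpha = 0.05)
  expect_equal(rep$consistent[rep$feature_id == "M1"], "enriched")
  expect_equal(rep$consistent[rep$feature_id == "M2"], "none")
  rep2 <- consistencyReport(tabs, min_frac = 0.6)
  expect_equal(rep2$consistent[rep2$feature_id == "M2"], "depleted")
})
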