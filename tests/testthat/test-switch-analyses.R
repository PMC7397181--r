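test_that("length ratios are categorized and tested against binomial", {
  ex <- GenomicRanges::GRangesList(
    a1 = GenomicRanges::GRanges("c1", IRanges::IRanges(1, 4000), strand = "+"),
    a2 = GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1000), strand = "+"),
    b1 = GenomicRanges::GRanges("c2", IRanges::IRanges(1, 500), strand = "+"),
    b2 = GenomicRanges::GRanges("c2", IRanges::IRanges(1, 500), strand = "+"))
  ts <- TranscriptSet(ex, gene_id = c("GA", "GA", "GB", "GB"))
  pairs <- data.frame(gene_id = c("GA", "GB"), tc_id = c("a1", "b1"),
                      tn_id = c("a2", "b2"))
  lr <- classifyLengthRatio(pairs, ts)
  expect_equal(lr$pairs$length_ratio_log2, c(2, 0))
  expect_equal(lr$pairs$category, c("positive", "neutral"))
  expect_equal(unname(lr$counts["positive"]), 1L)
  # binomial p for 30 positive vs 10 negative matches the exact test
  d <- dbinom(0:40, 40, 0.5)
  expect_equal(binomialTest(30, 40)$p_value,
               sum(d[d <= d[31] + 1e-12]), tolerance = 1e-9)
})

test_that("exon-count comparison uses Mood's test within a category", {
  # Tc with many exons, Tn with few: table fully separated
  mk <- function(n_ex, chrom) {
    st <- seq(1, by = 200, length.out = n_ex)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(st, st + 99),
                           strand = "+")
  }
  exl <- list(); gid <- character(0)
  pairs <- data.frame(gene_id = character(0), tc_id = character(0),
                      tn_id = character(0))
  for (i in 1:3) {
    tc <- sprintf("c%d", i); tn <- sprintf("n%d", i)
    exl[[tc]] <- mk(4 + i, sprintf("chr%d", i))
    exl[[tn]] <- mk(1, sprintf("chr%d", i))
    gid <- c(gid, sprintf("G%d", i), sprintf("G%d", i))
    pairs <- rbind(pairs, data.frame(gene_id = sprintf("G%d", i),
                                     tc_id = tc, tn_id = tn))
  }
  ts <- TranscriptSet(GenomicRanges::GRangesList(exl), gene_id = gid)
  pairs$category <- "positive"
  r <- compareExonCounts(pairs, ts, "positive")
  # 2x2 table (3,0;0,3): Fisher two-sided = 0.1
  expect_equal(r$p_value, 0.1, tolerance = 1e-9)
  expect_equal(r$direction, "x_greater")
  expect_error(compareExonCounts(pairs, ts, "negative"), "fewer than 2")
})

test_that("mono- vs multi-exonic deltaTU uses Welch's t-test", {
  # closed-form check on 2+2 values
  r <- welchTTest(c(-0.3, -0.4), c(0.3, 0.4))
  expect_equal(abs(r$estimate1 - r$estimate2), 0.7)
  expect_lt(r$p_value, 0.05)
  # fixture planting mono-exonic nuclear isoforms
  cfg <- simulationConfig(n_genes = 40, mono_nuclear = TRUE,
                          ri_nuclear_frac = 0, seed = 31)
  ann <- simulateAnnotation(cfg)
  fe <- simulateExpression(ann$ts, ann$truth, cfg)
  u <- empiricalPvalues(computeUsage(fe, ann$ts), fe)
  sw <- callSwitches(u)
  r2 <- compareMonoMulti(u, ann$ts, sw)
  # mono-exonic (x) nuclear, multi-exonic (y) cytoplasmic
  expect_lt(r2$estimate1, 0)
  expect_gt(r2$estimate2, 0)
  expect_lt(r2$p_value, 0.01)
})

test_that("biotype comparison is directional and skips degenerate input", {
  cfg <- simulationConfig(n_genes = 40, noncoding_nuclear = TRUE,
                          ri_nuclear_frac = 0, seed = 32)
  ann <- simulateAnnotation(cfg)
  fe <- simulateExpression(ann$ts, ann$truth, cfg)
  u <- computeUsage(fe, ann$ts)
  r <- compareBiotype(u, ann$ts)
  expect_gt(r$estimate1, r$estimate2)  # coding median > noncoding median
  expect_lt(r$p_value, 0.01)
  cfg2 <- simulationConfig(n_genes = 10, seed = 33)
  ann2 <- simulateAnnotation(cfg2)
  fe2 <- simulateExpression(ann2$ts, ann2$truth, cfg2)
  expect_warning(r2 <- compareBiotype(computeUsage(fe2, ann2$ts), ann2$ts),
                 "one biotype")
  expect_null(r2)
})

test_that("NMD sensitivity is the pseudo-counted log2 fold-change", {
  ts <- makeSEGene()
  ctrl <- makeExpression(ts, c(t1 = 10, t2 = 5), c(t1 = 10, t2 = 5))
  kd <- makeExpression(ts, c(t1 = 40, t2 = 5), c(t1 = 40, t2 = 5))
  s <- nmdSensitivity(ctrl, kd, pseudo = 1e-9)
  expect_equal(unname(s["t1"]), 2, tolerance = 1e-6)
  expect_equal(unname(s["t2"]), 0, tolerance = 1e-6)
  # mismatched transcript sets
  m <- matrix(1, 1, 4, dimnames = list("other",
                                       c("c1", "c2", "n1", "n2")))
  kd2 <- FractionExpression(m, rep(c("cytoplasm", "nucleus"), each = 2),
                            rep(1:2, 2))
  expect_error(nmdSensitivity(ctrl, kd2), "different transcripts")
})

test_that("localization-independent decay gives mostly non-significant NMD tests", {
  sig <- 0
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    cfg <- simulationConfig(n_genes = 40, ri_nuclear_frac = 0, seed = 100 + seed)
    ann <- simulateAnnotation(cfg)
    fe <- simulateExpression(ann$ts, ann$truth, cfg)
    kd <- simulateKnockdown(fe, cfg)
    u <- empiricalPvalues(computeUsage(fe, ann$ts), fe)
    sw <- callSwitches(u)
    if (nrow(sw) < 4) next
    r <- compareNMD(nmdSensitivity(fe, kd), sw)
    if (r$p_value < 0.05) sig <- sig + 1
  }
  expect_lte(sig, 0.1 * n_seeds + 1e-9)
})
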