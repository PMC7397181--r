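test_that("usage follows the TPM-share definition", {
  ts <- makeSEGene()
  fe <- makeExpression(ts, c(t1 = 30, t2 = 30), c(t1 = 10, t2 = 40))
  u <- computeUsage(fe, ts)
  expect_equal(u$tu_cyto[u$transcript_id == "t1"], 0.5)
  expect_equal(u$tu_nuc[u$transcript_id == "t1"], 0.2)
  expect_equal(u$delta_tu[u$transcript_id == "t1"], 0.3)
  # per-gene conservation
  expect_equal(sum(u$delta_tu), 0)
})

test_that("single-isoform genes have usage 1 and deltaTU 0", {
  ex <- GenomicRanges::GRangesList(
    s1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
                                strand = "+"))
  ts <- TranscriptSet(ex, gene_id = "G1")
  fe <- makeExpression(ts, c(s1 = 7), c(s1 = 3))
  u <- computeUsage(fe, ts)
  expect_equal(u$tu_cyto, 1)
  expect_equal(u$tu_nuc, 1)
  expect_equal(u$delta_tu, 0)
})

test_that("low-expression genes are excluded with a count", {
  ts <- makeSEGene()
  fe <- makeExpression(ts, c(t1 = 0.3, t2 = 0.3), c(t1 = 10, t2 = 10))
  u <- computeUsage(fe, ts)
  expect_equal(nrow(u), 0L)
  expect_equal(attr(u, "excluded_genes"), 1L)
})

test_that("TU sums to 1 and deltaTU sums to 0 per gene on random tables", {
  for (seed in 1:10) {
    d <- randomUsageTable(seed)
    u <- computeUsage(d$fe, d$ts)
    sums_c <- tapply(u$tu_cyto, u$gene_id, sum)
    sums_n <- tapply(u$tu_nuc, u$gene_id, sum)
    sums_d <- tapply(u$delta_tu, u$gene_id, sum)
    expect_true(all(abs(sums_c - 1) < 1e-9))
    expect_true(all(abs(sums_n - 1) < 1e-9))
    expect_true(all(abs(sums_d) < 1e-9))
  }
})

test_that("empirical p-values need replicates and honour the rank rule", {
  ts <- makeSEGene()
  fe1 <- makeExpression(ts, c(t1 = 30, t2 = 30), c(t1 = 10, t2 = 40),
                        nr = 1)
  u1 <- computeUsage(fe1, ts)
  expect_error(empiricalPvalues(u1, fe1), "replicates")
  # observed deltaTU of 0 gets p = 1 under any null
  fe <- makeExpression(ts, c(t1 = 30, t2 = 30), c(t1 = 30, t2 = 30))
  u <- empiricalPvalues(computeUsage(fe, ts), fe)
  expect_equal(u$p_value, c(1, 1))
})

test_that("fraction swap negates deltaTU and preserves p and pair roles", {
  d <- randomUsageTable(21)
  u <- empiricalPvalues(computeUsage(d$fe, d$ts), d$fe)
  us <- empiricalPvalues(computeUsage(swapFractions(d$fe), d$ts),
                         swapFractions(d$fe))
  expect_equal(us$delta_tu, -u$delta_tu)
  expect_equal(us$p_value, u$p_value)
  sw <- callSwitches(u, threshold = 0.1, alpha = 0.5)
  sws <- callSwitches(us, threshold = 0.1, alpha = 0.5)
  expect_equal(sw$tc_id, sws$tn_id)
  expect_equal(sw$tn_id, sws$tc_id)
})

test_that("switch calling applies both thresholds and is monotone", {
  usage <- data.frame(
    transcript_id = c("a", "b", "c", "d", "e"),
    gene_id = c("G1", "G1", "G1", "G2", "G2"),
    tu_cyto = 0, tu_nuc = 0,
    delta_tu = c(0.5, -0.4, 0.1, 0.6, -0.1),
    p_value = c(0.01, 0.02, 0.3, 0.01, 0.01))
  sw <- callSwitches(usage)
  # G1 pairs (a, b); G2 has no significant negative side
  expect_equal(sw$gene_id, "G1")
  expect_equal(sw$tc_id, "a")
  expect_equal(sw$tn_id, "b")
  # raising the threshold or lowering alpha never adds pairs
  for (thr in c(0.2, 0.3, 0.45)) {
    for (al in c(0.05, 0.015)) {
      n1 <- nrow(callSwitches(usage, thr, al))
      n2 <- nrow(callSwitches(usage, thr + 0.1, al))
      n3 <- nrow(callSwitches(usage, thr, al / 2))
      expect_lte(n2, n1)
      expect_lte(n3, n1)
    }
  }
})

test_that("shared switching genes joins across datasets", {
  tabs <- lapply(1:6, function(i)
    data.frame(gene_id = c("G1", sprintf("G%d", i + 1))))
  out <- sharedSwitchingGenes(tabs, k = 5)
  expect_equal(out$gene_id, "G1")
  expect_equal(out$n_datasets, 6L)
})
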