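test_that("configs validate proportions, mixes and feasibility", {
  expect_error(simulationConfig(frac_switching_genes = 1.2), "proportions")
  expect_error(simulationConfig(event_mix = c(A3 = 0.5, A5 = 0.5, AF = 0,
                                              AL = 0, MX = 0, RI = 0.5,
                                              SE = -0.5)), "sum to 1|\\[0, 1\\]")
  expect_error(simulationConfig(ri_short_len = 30), "at least 60")
  expect_error(simulationConfig(max_exons = 3), "MX events")
  mix <- c(A3 = 1, A5 = 0, AF = 0, AL = 0, MX = 0, RI = 0, SE = 0)
  expect_s3_class(simulationConfig(event_mix = mix, max_exons = 2),
                  "SimulationConfig")
})

test_that("identical config and seed give byte-identical bundles", {
  cfg <- simulationConfig(n_genes = 8, seed = 9,
                          planted_motifs = "M1",
                          repeat_nuclear_rate = 0.5, repeat_bg_rate = 0.2,
                          ri_nuclear_frac = 1)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  b1 <- bundleFixture(cfg, d1)
  b2 <- bundleFixture(cfg, d2)
  for (nm in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]),
                     info = nm)
  }
})

test_that("bundles round-trip through the readers", {
  cfg <- simulationConfig(n_genes = 10, seed = 10, planted_motifs = "M2",
                          repeat_nuclear_rate = 1, ri_nuclear_frac = 1)
  dir <- file.path(tempdir(), "fx3")
  b <- bundleFixture(cfg, dir)
  ts <- readGTF(b$paths$gtf)
  expect_equal(sort(transcriptIds(ts)), sort(transcriptIds(b$ts)))
  expect_equal(SpliceLoc:::.exonMatrices(ts)[transcriptIds(b$ts)],
               SpliceLoc:::.exonMatrices(b$ts))
  meta <- utils::read.delim(paste0(b$paths$expression, ".meta"))
  fe <- readExpression(b$paths$expression, meta)
  expect_equal(tpm(fe), tpm(b$fe), tolerance = 1e-6)
  genome <- readFASTA(b$paths$fasta)
  expect_equal(sort(names(genome)), sort(names(b$genome)))
  reps <- readBED(b$paths$bed)
  expect_equal(length(reps), length(b$repeats))
  pw <- readPWMs(b$paths$pwms)
  expect_equal(names(pw), names(makeTestPWMs()))
})

test_that("all generated introns carry GT..AG on the transcribed strand", {
  cfg <- simulationConfig(n_genes = 25, seed = 12)
  ann <- simulateAnnotation(cfg)
  sq <- simulateSequences(ann$ts, ann$truth, cfg)
  inl <- txIntrons(ann$ts)
  for (t in names(inl)) {
    if (length(inl[[t]]) == 0) next
    seqs <- as.character(intronSequences(inl[[t]], sq$genome))
    expect_true(all(substr(seqs, 1, 2) == "GU"), info = t)
    expect_true(all(substr(seqs, nchar(seqs) - 1, nchar(seqs)) == "AG"),
                info = t)
  }
})

test_that("nuclear RI interiors carry the configured GC boost", {
  cfg <- simulationConfig(n_genes = 220, seed = 13, ri_nuclear_frac = 0.5,
                          event_mix = c(A3 = 0, A5 = 0, AF = 0, AL = 0,
                                        MX = 0, RI = 1, SE = 0),
                          ri_short_len = 200, ri_bg_len = 200,
                          ri_stem_len = 0, ri_gc_boost = 0.15)
  ann <- simulateAnnotation(cfg)
  sq <- simulateSequences(ann$ts, ann$truth, cfg)
  tg <- sq$truth$genes
  gcof <- function(rows) {
    gr <- GenomicRanges::GRanges(rows$chrom,
                                 IRanges::IRanges(rows$event_start,
                                                  rows$event_end),
                                 strand = rows$strand)
    pr <- intronProfiles(gr, sq$genome, structure = FALSE)
    pr$gc
  }
  gn <- gcof(tg[tg$is_nuclear_ri, ])
  gb <- gcof(tg[!tg$is_nuclear_ri, ])
  diff <- mean(gn) - mean(gb)
  se <- sqrt(var(gn) / length(gn) + var(gb) / length(gb))
  expect_lt(abs(diff - 0.15), 2 * se + 0.02)
})

test_that("planted motif positions are recorded and present in sequence", {
  cfg <- simulationConfig(n_genes = 30, seed = 14, ri_nuclear_frac = 1,
                          event_mix = c(A3 = 0, A5 = 0, AF = 0, AL = 0,
                                        MX = 0, RI = 1, SE = 0),
                          planted_motifs = "M1", ri_short_len = 200,
                          ri_bg_len = 200)
  pw <- makeTestPWMs()
  ann <- simulateAnnotation(cfg)
  sq <- simulateSequences(ann$ts, ann$truth, cfg, pw)
  mp <- sq$truth$motif_positions
  expect_gt(nrow(mp), 0)
  tg <- sq$truth$genes
  for (i in seq_len(nrow(mp))) {
    row <- tg[tg$gene_id == mp$gene_id[i], ]
    gr <- GenomicRanges::GRanges(row$chrom,
                                 IRanges::IRanges(row$event_start,
                                                  row$event_end),
                                 strand = row$strand)
    s <- as.character(intronSequences(gr, sq$genome)[[1]])
    expect_equal(substr(s, mp$offset[i], mp$offset[i] + 5), "GCAUGC")
  }
})

test_that("noiseless expression reproduces planted usage exactly", {
  cfg <- simulationConfig(n_genes = 15, noise_cv = 0, seed = 15,
                          ri_nuclear_frac = 0)
  ann <- simulateAnnotation(cfg)
  fe <- simulateExpression(ann$ts, ann$truth, cfg)
  u <- computeUsage(fe, ann$ts)
  tg <- ann$truth$genes
  dt <- u$delta_tu[match(tg$tc_id[tg$is_switching], u$transcript_id)]
  expect_equal(dt, rep(0.5, sum(tg$is_switching)), tolerance = 1e-12)
  others <- u$delta_tu[u$gene_id %in% tg$gene_id[!tg$is_switching]]
  expect_equal(others, rep(0, length(others)), tolerance = 1e-12)
})

test_that("noisy deltaTU recovery is unbiased near the planted effect", {
  cfg <- simulationConfig(n_genes = 200, noise_cv = 0.1, n_replicates = 3,
                          frac_switching_genes = 0.5, ri_nuclear_frac = 0,
                          seed = 16)
  ann <- simulateAnnotation(cfg)
  fe <- simulateExpression(ann$ts, ann$truth, cfg)
  u <- computeUsage(fe, ann$ts)
  tg <- ann$truth$genes
  dt <- u$delta_tu[match(tg$tc_id[tg$is_switching], u$transcript_id)]
  expect_lt(abs(mean(dt, na.rm = TRUE) - 0.5), 0.05)
})
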