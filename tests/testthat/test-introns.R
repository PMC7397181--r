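test_that("boundary matrices reflect canonical GT..AG construction", {
  cfg <- simulationConfig(n_genes = 30, seed = 51,
                          event_mix = c(A3 = 0, A5 = 0, AF = 0, AL = 0,
                                        MX = 0, RI = 1, SE = 0),
                          ri_short_len = 200, ri_bg_len = 200)
  ann <- simulateAnnotation(cfg)
  sq <- simulateSequences(ann$ts, ann$truth, cfg)
  tg <- sq$truth$genes
  gr <- GenomicRanges::GRanges(tg$chrom,
                               IRanges::IRanges(tg$event_start,
                                                tg$event_end),
                               strand = tg$strand)
  bm <- boundaryMatrices(gr, sq$genome)
  # donor window: 3 exonic then G T
  expect_equal(unname(bm$donor["G", 4]), 1)
  expect_equal(unname(bm$donor["U", 5]), 1)
  # acceptor window: ...A G then 3 exonic
  expect_equal(unname(bm$acceptor["A", 8]), 1)
  expect_equal(unname(bm$acceptor["G", 9]), 1)
  expect_equal(colSums(bm$donor), rep(1, 12), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical input sets give distance 0
  expect_equal(max(boundaryDistance(bm$donor, bm$donor)), 0)
})

test_that("short introns are excluded from boundary windows with a count", {
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("A", 60)))
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(10, 30), c(14, 50)),
                               strand = "+")
  bm <- boundaryMatrices(gr, genome)
  expect_equal(attr(bm, "excluded"), 1L)
  expect_equal(attr(bm, "n"), 1L)
})

test_that("feature comparisons are Welch tests with documented scales", {
  a <- data.frame(length = c(100, 120, 110), mean_stem_probability =
                    c(0.6, 0.62, 0.58))
  b <- data.frame(length = c(1000, 1200, 1100), mean_stem_probability =
                    c(0.5, 0.52, 0.48))
  r <- compareFeature(a, b, "length")
  expect_lt(r$p_value, 0.01)
  expect_equal(r$direction, "y_greater")       # log10 lengths larger in b
  expect_equal(r$estimate1, mean(log10(a$length)))
  r2 <- compareFeature(a, b, "mean_stem_probability")
  expect_equal(r2$direction, "x_greater")
  expect_equal(compareFeature(a, a, "length")$p_value, 1)
  expect_error(compareFeature(a[1, ], b, "length"), "at least 2")
})

test_that("dinucleotide ratios are 1 for identical sets and track composition", {
  set.seed(52)
  seqs <- Biostrings::RNAStringSet(vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "U"), 100, replace = TRUE),
          collapse = ""), character(1)))
  r <- dinucleotideEnrichment(seqs, seqs)
  expect_equal(unname(r), rep(1, 16))
  # GC-only target vs uniform background
  gc <- Biostrings::RNAStringSet(rep(strrep("GC", 50), 5))
  r2 <- dinucleotideEnrichment(gc, seqs)
  expect_gt(r2[["GC"]], 5)
  expect_gt(r2[["CG"]], 5)
  expect_equal(r2[["AA"]], 0)
  # reverse-complement invariance when both sets are transformed:
  # a dinucleotide XY maps to comp(Y)comp(X), so GC -> GC and AC -> GU
  rc <- function(x) Biostrings::reverseComplement(x)
  r3 <- dinucleotideEnrichment(rc(gc), rc(seqs))
  expect_equal(r3[["GC"]], r2[["GC"]], tolerance = 1e-12)
  expect_equal(r3[["GU"]], r2[["AC"]], tolerance = 1e-12)
})

test_that("intron profiles carry length, GC and sequences", {
  genome <- Biostrings::DNAStringSet(c(c1 = "AAGTGGGCCCAGAA"))
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(3, 13), strand = "+")
  names(gr) <- "i1"
  pr <- intronProfiles(gr, genome, structure = FALSE)
  expect_equal(pr$length, 11L)
  expect_equal(pr$gc, 8 / 11, tolerance = 1e-12)
  expect_equal(as.character(attr(pr, "sequences")[[1]]), "GUGGGCCCAGA")
})
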