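# Hand-built micro fixtures used by the unit tests.

# one gene, two isoforms: t1 = 3 exons, t2 skips the middle exon
makeSEGene <- function(strand = "+") {
  ex <- GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(101, 301, 501), c(200, 400, 600)),
      strand = strand),
    t2 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(101, 501), c(200, 600)), strand = strand))
  TranscriptSet(ex, gene_id = c("G1", "G1"))
}

# one gene, two isoforms: t1 spliced (2 exons), t2 retains the intron
makeRIGene <- function(strand = "+") {
  ex <- GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(101, 301), c(200, 400)), strand = strand),
    t2 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(101, 400), strand = strand))
  TranscriptSet(ex, gene_id = c("G1", "G1"))
}

# expression over a TranscriptSet: named per-fraction means, nr replicates,
# no noise
makeExpression <- function(ts, mean_cyto, mean_nuc, nr = 2) {
  ids <- transcriptIds(ts)
  m <- cbind(matrix(rep(mean_cyto[ids], nr), ncol = nr),
             matrix(rep(mean_nuc[ids], nr), ncol = nr))
  rownames(m) <- ids
  colnames(m) <- c(sprintf("c%d", seq_len(nr)), sprintf("n%d", seq_len(nr)))
  FractionExpression(m, rep(c("cytoplasm", "nucleus"), each = nr),
                     rep(seq_len(nr), 2))
}
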