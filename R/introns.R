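#' Per-intron feature profiles
#'
#' Length, GC content, dinucleotide counts and (optionally) mean stem
#' probability for a set of introns, with sequences taken strand-aware from
#' the genome.
#'
#' @param introns GRanges of introns (named; strand set).
#' @param genome DNAStringSet of chromosome sequences.
#' @param structure compute mean stem probabilities (can be slow for long
#'   introns), default TRUE.
#' @param cap folding window cap passed to [meanStemProbability()].
#' @return data.frame with intron_id, chrom, start, end, strand, length,
#'   gc, mean_stem_probability; the RNA sequences are attached as attribute
#'   \code{"sequences"} (RNAStringSet).
#' @export
intronProfiles <- function(introns, genome, structure = TRUE, cap = 2000) {
  seqs <- intronSequences(introns, genome)
  freq <- Biostrings::alphabetFrequency(seqs)
  if (is.null(dim(freq))) freq <- matrix(freq, nrow = 1,
                                         dimnames = list(NULL, names(freq)))
  gc <- (freq[, "C"] + freq[, "G"]) /
    pmax(rowSums(freq[, c("A", "C", "G", "U"), drop = FALSE]), 1)
  msp <- if (structure)
    vapply(as.character(seqs), meanStemProbability, numeric(1), cap = cap,
           USE.NAMES = FALSE)
  else rep(NA_real_, length(seqs))
  out <- data.frame(intron_id = names(seqs),
                    chrom = as.character(seqnames(introns)),
                    start = start(introns), end = end(introns),
                    strand = as.character(strand(introns)),
                    length = width(introns), gc = as.numeric(gc),
                    mean_stem_probability = msp,
                    stringsAsFactors = FALSE)
  attr(out, "sequences") <- seqs
  out
}

#' Splice-site boundary frequency matrices
#'
#' Position-frequency matrices over the donor (exon|intron) and acceptor
#' (intron|exon) boundary windows, strand-resolved so position 1 is always
#' the transcribed-strand 5'-most base. Defaults follow the common logo
#' convention: 3 exonic + 9 intronic bases at the donor, 9 intronic + 3
#' exonic at the acceptor. Introns shorter than the intronic window (or
#' without enough exonic flank on the chromosome) are excluded and counted
#' in attribute \code{"excluded"}.
#'
#' @param introns GRanges of introns.
#' @param genome DNAStringSet.
#' @param exonic,intronic window widths in nt.
#' @return list with \code{donor} and \code{acceptor} 4 x (exonic+intronic)
#'   frequency matrices (rows A, C, G, U).
#' @export
boundaryMatrices <- function(introns, genome, exonic = 3, intronic = 9) {
  win <- exonic + intronic
  donor <- character(0); acceptor <- character(0)
  excluded <- 0L
  for (i in seq_along(introns)) {
    chr <- as.character(seqnames(introns))[i]
    s <- start(introns)[i]; e <- end(introns)[i]
    st <- as.character(strand(introns))[i]
    clen <- length(genome[[chr]])
    if (width(introns)[i] < intronic || s - exonic < 1 ||
        e + exonic > clen) {
      excluded <- excluded + 1L
      next
    }
    if (st == "+") {
      d <- Biostrings::subseq(genome[[chr]], s - exonic, s + intronic - 1)
      a <- Biostrings::subseq(genome[[chr]], e - intronic + 1, e + exonic)
    } else {
      d <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chr]], e - intronic + 1, e + exonic))
      a <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chr]], s - exonic, s + intronic - 1))
    }
    donor <- c(donor, as.character(d))
    acceptor <- c(acceptor, as.character(a))
  }
  if (length(donor) == 0) stop("no introns long enough for boundary windows")
  toMat <- function(x) {
    m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(x),
                                     baseOnly = TRUE)[1:4, , drop = FALSE]
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- c("A", "C", "G", "U")
    m
  }
  out <- list(donor = toMat(donor), acceptor = toMat(acceptor))
  attr(out, "excluded") <- excluded
  attr(out, "n") <- length(donor)
  out
}

#' Per-position total-variation distance between two boundary matrices
#'
#' @param m1,m2 4 x width frequency matrices with matching dimensions.
#' @return numeric vector of per-position TV distances (0.5 * L1).
#' @export
boundaryDistance <- function(m1, m2) {
  stopifnot(identical(dim(m1), dim(m2)))
  colSums(abs(m1 - m2)) / 2
}

#' Compare a feature between nuclear RIs and the background RI set
#'
#' Welch two-tailed t-test on intron length (log10 scale; intron lengths
#' are heavy-tailed) or mean stem probability.
#'
#' @param nuclear_profiles,background_profiles data.frames from
#'   [intronProfiles()].
#' @param feature \code{"length"} or \code{"mean_stem_probability"}.
#' @return test-result data.frame (x = nuclear, y = background); estimates
#'   are group means on the tested scale.
#' @export
compareFeature <- function(nuclear_profiles, background_profiles,
                           feature = c("length", "mean_stem_probability")) {
  feature <- match.arg(feature)
  x <- nuclear_profiles[[feature]]
  y <- background_profiles[[feature]]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 introns per set")
  if (feature == "length") {
    x <- log10(x); y <- log10(y)
  }
  welchTTest(x, y)
}

#' Normalized dinucleotide frequencies
#'
#' Frequency of each of the 16 dinucleotides in the target introns divided
#' by its frequency in the background introns; frequencies are computed
#' over pooled counts (concatenated within-intron dinucleotides), not
#' per-intron means. A ratio of 1 means no preference; background
#' dinucleotides never observed give NA.
#'
#' @param target_seqs,background_seqs RNAStringSet (or character) of intron
#'   sequences.
#' @return named numeric vector of 16 ratios (AA, AC, ..., UU).
#' @export
dinucleotideEnrichment <- function(target_seqs, background_seqs) {
  countAll <- function(seqs) {
    seqs <- Biostrings::RNAStringSet(seqs)
    colSums(Biostrings::dinucleotideFrequency(seqs))
  }
  tc <- countAll(target_seqs)
  bc <- countAll(background_seqs)
  tf <- tc / sum(tc)
  bf <- bc / sum(bc)
  ratio <- tf / bf
  ratio[bf == 0] <- NA_real_
  ratio
}
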