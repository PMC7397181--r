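#' Read transcript models from a GTF file
#'
#' Only \code{exon} features are used; each must carry \code{gene_id} and
#' \code{transcript_id} attributes. The transcript biotype is taken from the
#' \code{transcript_type} attribute when present (anything other than
#' \code{"protein_coding"} counts as noncoding), else \code{"coding"}.
#' Malformed lines are rejected with the offending line number rather than
#' silently repaired.
#'
#' @param path GTF file path.
#' @return A \linkS4class{TranscriptSet}.
#' @export
readGTF <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields", bad))
  }
  exon_line <- body & grepl("\t(exon)\t", lines, perl = TRUE)
  no_tx <- exon_line & !grepl("transcript_id", lines, fixed = TRUE)
  if (any(no_tx))
    stop(sprintf("GTF line %d: exon feature without transcript_id",
                 which(no_tx)[1]))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("GTF contains no exon features")
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("exon feature without transcript_id")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon feature without gene_id")
  sp <- split(gr, gr$transcript_id)
  biotype <- vapply(sp, function(g) {
    tt <- if (!is.null(g$transcript_type)) g$transcript_type[1] else NA
    if (is.na(tt) || tt %in% c("protein_coding", "coding")) "coding"
    else "noncoding"
  }, character(1))
  gene <- vapply(sp, function(g) g$gene_id[1], character(1))
  exl <- GRangesList(lapply(sp, function(g) {
    g <- g[order(start(g))]
    mcols(g) <- NULL
    g
  }))
  TranscriptSet(exl, gene_id = gene, biotype = biotype)
}

#' Write a TranscriptSet as GTF
#'
#' Emits one \code{exon} feature per exon with \code{gene_id},
#' \code{transcript_id} and \code{transcript_type} attributes, so that
#' \code{readGTF(writeGTF(x))} round-trips.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGTF <- function(ts, path) {
  ex <- txExons(ts)
  n <- lengths(ex)
  gr <- unlist(ex, use.names = FALSE)
  mcols(gr) <- DataFrame(
    source = "SpliceLoc", type = "exon",
    gene_id = rep(unname(geneIds(ts)), n),
    transcript_id = rep(transcriptIds(ts), n),
    transcript_type = rep(ifelse(txBiotype(ts) == "coding",
                                 "protein_coding", "lncRNA"), n))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a transcript x sample TPM table
#'
#' TSV with a first column of transcript ids and one column per sample.
#' Every sample column must be described in \code{meta}; negative or missing
#' TPM values are rejected.
#'
#' @param path TSV file path.
#' @param meta data.frame with columns \code{sample_id}, \code{fraction}
#'   (\code{"cytoplasm"}/\code{"nucleus"}) and \code{replicate}.
#' @return A \linkS4class{FractionExpression}.
#' @export
readExpression <- function(path, meta) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs transcript ids plus samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicated transcript ids in expression table")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric TPM values")
  if (anyNA(m)) stop("missing TPM values are not allowed")
  if (any(m < 0)) stop("negative TPM values are not allowed")
  rownames(m) <- ids
  missing_meta <- setdiff(colnames(m), meta$sample_id)
  if (length(missing_meta))
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  idx <- match(colnames(m), meta$sample_id)
  FractionExpression(m, meta$fraction[idx], meta$replicate[idx])
}

#' Write a FractionExpression as TSV (plus sample metadata)
#' @param fe A \linkS4class{FractionExpression}.
#' @param path output TSV path; metadata goes to \code{paste0(path, ".meta")}.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(fe, path) {
  tab <- data.frame(transcript_id = rownames(fe), tpm(fe),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(fe),
                     fraction = sampleFractions(fe),
                     replicate = colData(fe)$replicate)
  utils::write.table(meta, paste0(path, ".meta"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genome (or transcript) sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A \code{DNAStringSet} named by sequence id; duplicate ids are an
#'   error.
#' @export
readFASTA <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA sequence ids")
  seqs
}

.repeatClasses <- c("SINE", "LINE", "LTR", "DNA", "other")

#' Read a repeat annotation from BED4
#'
#' BED intervals (0-based half-open on disk) with the repeat class in column
#' 4; returned as a GRanges (1-based closed) with an \code{repeat_class}
#' metadata column drawn from \code{SINE, LINE, LTR, DNA, other}.
#'
#' @param path BED file path.
#' @return GRanges with \code{repeat_class}.
#' @export
readBED <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(GRanges(seqnames = character(0), ranges = IRanges(),
                   repeat_class = character(0)))
  f <- strsplit(lines, "\\s+")
  if (any(lengths(f) < 4)) stop("BED line with fewer than 4 fields")
  s <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  if (anyNA(s) || anyNA(e)) stop("non-numeric BED coordinates")
  if (any(s >= e)) stop("BED interval with start >= end")
  cls <- vapply(f, `[`, "", 4L)
  bad <- setdiff(unique(cls), .repeatClasses)
  if (length(bad))
    stop("unknown repeat class: ", paste(bad, collapse = ", "))
  gr <- rtracklayer::import(path, format = "bed")
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
  out$repeat_class <- gr$name
  out
}

#' Write a repeat annotation as BED4
#' @param repeats GRanges with \code{repeat_class}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBED <- function(repeats, path) {
  df <- data.frame(chrom = as.character(seqnames(repeats)),
                   start = start(repeats) - 1L, end = end(repeats),
                   name = repeats$repeat_class)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read position weight matrices
#'
#' Simple text format: a header line \code{">motif_id rbp_name"} followed by
#' one line per motif position with four whitespace-separated probabilities
#' in A C G U order. Each row must sum to 1 (tolerance 1e-9) and motifs must
#' be at least 4 positions long.
#'
#' @param path PWM file path.
#' @return named list of 4 x width probability matrices (rownames A,C,G,U)
#'   with an \code{rbp_name} attribute each.
#' @export
readPWMs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no PWM headers ('>') found")
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    hd <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]]
    rows <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    vals <- lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
    if (any(lengths(vals) != 4))
      stop("PWM row without exactly 4 probabilities in motif ", hd[1])
    m <- t(do.call(rbind, vals))
    rownames(m) <- c("A", "C", "G", "U")
    out[[hd[1]]] <- .validatePWM(m, hd[1],
                                 rbp = if (length(hd) > 1) hd[2] else hd[1])
  }
  out
}

.validatePWM <- function(m, id, rbp = id) {
  if (ncol(m) < 4) stop("PWM ", id, " shorter than 4 positions")
  if (any(abs(colSums(m) - 1) > 1e-9))
    stop("PWM ", id, " has a position not summing to 1")
  if (any(m < 0)) stop("PWM ", id, " has negative probabilities")
  attr(m, "rbp_name") <- rbp
  m
}

#' Write position weight matrices in the format read by [readPWMs()]
#' @param pwms named list of 4 x width matrices.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePWMs <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pwms)) {
    m <- pwms[[id]]
    writeLines(sprintf(">%s %s", id,
                       attr(m, "rbp_name") %||% id), con)
    utils::write.table(t(m), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write analysis result tables to a directory
#'
#' Writes whatever tables the pipeline produced (usage, switch pairs, events,
#' PSI, intron features, enrichments, ...) as TSV files named after the list
#' elements. List columns (e.g. event transcript sets) are collapsed with
#' commas.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
writeResults <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    df <- tables[[nm]]
    for (cl in colnames(df))
      if (is.list(df[[cl]]))
        df[[cl]] <- vapply(df[[cl]], paste, "", collapse = ",")
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Extract strand-aware intron sequences
#'
#' Returns the transcribed-strand sequence of each intron: minus-strand
#' introns are reverse-complemented, and T is presented as U (RNA alphabet)
#' so motif and structure analysis always see the transcribed sequence.
#'
#' @param introns GRanges of introns (strand set).
#' @param genome DNAStringSet of chromosome sequences.
#' @return RNAStringSet, one sequence per intron.
#' @export
intronSequences <- function(introns, genome) {
  chr <- as.character(seqnames(introns))
  miss <- setdiff(unique(chr), names(genome))
  if (length(miss)) stop("chromosome missing from genome: ",
                         paste(miss, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(introns), function(i) {
    s <- Biostrings::subseq(genome[[chr[i]]], start(introns)[i],
                            end(introns)[i])
    if (as.character(strand(introns))[i] == "-")
      s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1)))
  names(seqs) <- if (!is.null(names(introns))) names(introns) else
    sprintf("%s:%d-%d:%s", chr, start(introns), end(introns),
            as.character(strand(introns)))
  Biostrings::RNAStringSet(seqs)
}
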