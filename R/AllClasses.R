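#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRangesList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList start end width strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' TranscriptSet: exon models for a set of transcripts
#'
#' Container for transcript exon structures parsed from a GTF annotation.
#' Exons are held as a \linkS4class{GRangesList} (one element per transcript,
#' 1-based closed coordinates, sorted by start), alongside per-transcript
#' metadata: \code{gene_id} and \code{biotype} (\code{"coding"} or
#' \code{"noncoding"}). Introns are derived as the gaps between consecutive
#' exons; a mono-exonic transcript has none.
#'
#' @slot exons GRangesList of exons, names are transcript ids.
#' @slot txData DataFrame with columns \code{transcript_id}, \code{gene_id},
#'   \code{biotype}, one row per transcript, in the same order as
#'   \code{exons}.
#' @export
setClass("TranscriptSet",
  representation(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    return("exons and txData describe different numbers of transcripts")
  if (!all(c("transcript_id", "gene_id", "biotype") %in% colnames(td)))
    return("txData must have transcript_id, gene_id and biotype columns")
  if (!identical(names(ex), as.character(td$transcript_id)))
    return("names(exons) must equal txData$transcript_id")
  if (anyDuplicated(td$transcript_id))
    return("duplicated transcript ids")
  bad <- !td$biotype %in% c("coding", "noncoding")
  if (any(bad))
    return("biotype must be 'coding' or 'noncoding'")
  st <- unlist(start(ex), use.names = FALSE)
  en <- unlist(end(ex), use.names = FALSE)
  if (any(en < st)) return("exon end < start")
  # sorted, non-overlapping within each transcript
  for (i in seq_along(ex)) {
    g <- ex[[i]]
    if (length(g) > 1) {
      s <- start(g); e <- end(g)
      if (is.unsorted(s, strictly = TRUE))
        return(sprintf("exons of %s not sorted by start", names(ex)[i]))
      if (any(s[-1] <= e[-length(e)]))
        return(sprintf("overlapping exons in %s", names(ex)[i]))
      if (length(unique(as.character(strand(g)))) != 1 ||
          length(unique(as.character(seqnames(g)))) != 1)
        return(sprintf("%s mixes strands or chromosomes", names(ex)[i]))
    }
  }
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons GRangesList of exons, one element per transcript (any order
#'   within transcripts; exons are sorted by start).
#' @param gene_id character vector of gene ids, one per transcript.
#' @param biotype character vector, \code{"coding"} (default) or
#'   \code{"noncoding"}, recycled.
#' @return A \linkS4class{TranscriptSet}.
#' @export
TranscriptSet <- function(exons, gene_id, biotype = "coding") {
  if (is.null(names(exons))) stop("exons must be named by transcript id")
  exons <- GRangesList(lapply(exons, function(g) g[order(start(g))]),
                       compress = TRUE)
  td <- DataFrame(transcript_id = names(exons),
                  gene_id = as.character(gene_id),
                  biotype = rep_len(as.character(biotype), length(exons)))
  new("TranscriptSet", exons = exons, txData = td)
}

#' FractionExpression: transcript TPM across subcellular fractions
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"TPM"}
#' (transcripts x samples, non-negative) whose \code{colData} carries the
#' subcellular \code{fraction} (\code{"cytoplasm"} or \code{"nucleus"}) and
#' integer \code{replicate} index of each sample.
#'
#' @export
setClass("FractionExpression", contains = "SummarizedExperiment")

setValidity("FractionExpression", function(object) {
  if (!"TPM" %in% SummarizedExperiment::assayNames(object))
    return("assay 'TPM' is required")
  m <- assay(object, "TPM")
  if (any(is.na(m))) return("TPM values must not be missing")
  if (any(m < 0)) return("TPM values must be non-negative")
  cd <- colData(object)
  if (!all(c("fraction", "replicate") %in% colnames(cd)))
    return("colData must have 'fraction' and 'replicate'")
  if (!all(cd$fraction %in% c("cytoplasm", "nucleus")))
    return("fraction must be 'cytoplasm' or 'nucleus'")
  if (!all(c("cytoplasm", "nucleus") %in% cd$fraction))
    return("both fractions need at least one sample")
  if (is.null(rownames(object))) return("transcript ids (rownames) required")
  TRUE
})

#' Construct a FractionExpression object
#'
#' @param tpm numeric matrix, transcripts x samples, rownames are transcript
#'   ids, colnames sample ids.
#' @param fraction character vector per sample, \code{"cytoplasm"} or
#'   \code{"nucleus"}.
#' @param replicate integer replicate index per sample.
#' @return A \linkS4class{FractionExpression}.
#' @export
FractionExpression <- function(tpm, fraction, replicate) {
  se <- SummarizedExperiment(
    assays = list(TPM = as.matrix(tpm)),
    colData = DataFrame(fraction = as.character(fraction),
                        replicate = as.integer(replicate),
                        row.names = colnames(tpm)))
  new("FractionExpression", se)
}
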