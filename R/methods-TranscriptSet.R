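#' Accessors for TranscriptSet
#'
#' \code{transcriptIds}/\code{geneIds}/\code{txBiotype} return per-transcript
#' metadata; \code{txExons} the exon GRangesList; \code{txIntrons} the derived
#' intron GRangesList (gaps between consecutive exons, 1-based closed;
#' mono-exonic transcripts get a zero-length element); \code{txLengths} the
#' summed exon length of each transcript; \code{exonCounts} the number of
#' exons.
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @name TranscriptSet-accessors
NULL

#' @rdname TranscriptSet-accessors
#' @export
setMethod("transcriptIds", "TranscriptSet", function(x)
  as.character(x@txData$transcript_id))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("geneIds", "TranscriptSet", function(x) {
  out <- as.character(x@txData$gene_id)
  names(out) <- transcriptIds(x)
  out
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txBiotype", "TranscriptSet", function(x) {
  out <- as.character(x@txData$biotype)
  names(out) <- transcriptIds(x)
  out
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txExons", "TranscriptSet", function(x) x@exons)

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txIntrons", "TranscriptSet", function(x) {
  ex <- x@exons
  GRangesList(lapply(seq_along(ex), function(i) {
    g <- ex[[i]]
    if (length(g) < 2)
      return(GRanges(seqnames = character(0), ranges = IRanges(),
                     strand = character(0)))
    GRanges(seqnames = as.character(seqnames(g))[1],
            ranges = IRanges(start = end(g)[-length(g)] + 1L,
                             end = start(g)[-1] - 1L),
            strand = as.character(strand(g))[1])
  }))[] -> out
  names(out) <- names(ex)
  out
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txLengths", "TranscriptSet", function(x) {
  out <- vapply(width(x@exons), sum, integer(1))
  names(out) <- transcriptIds(x)
  out
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("exonCounts", "TranscriptSet", function(x) {
  out <- lengths(x@exons)
  names(out) <- transcriptIds(x)
  out
})

#' @export
#' @describeIn TranscriptSet Number of transcripts
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' Subset a TranscriptSet by transcript id or index
#' @param x TranscriptSet
#' @param i character transcript ids or integer/logical index
#' @param j,...,drop ignored
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, transcriptIds(x))
  new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts in",
      length(unique(object@txData$gene_id)), "genes\n")
  bt <- table(object@txData$biotype)
  cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
})

# exon structures as plain integer matrices (start,end), used by the event
# classifier and generator internals; names = transcript ids
.exonMatrices <- function(ts) {
  ex <- ts@exons
  out <- lapply(seq_along(ex), function(i)
    cbind(start = start(ex[[i]]), end = end(ex[[i]])))
  names(out) <- names(ex)
  out
}

.intronMatrix <- function(exmat) {
  if (nrow(exmat) < 2)
    return(cbind(start = integer(0), end = integer(0)))
  cbind(start = exmat[-nrow(exmat), "end"] + 1L,
        end = exmat[-1, "start"] - 1L)
}
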