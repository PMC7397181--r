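#' @rdname TranscriptSet-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txBiotype", function(x) standardGeneric("txBiotype"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txIntrons", function(x) standardGeneric("txIntrons"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("exonCounts", function(x) standardGeneric("exonCounts"))

#' @rdname FractionExpression-accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @rdname FractionExpression-accessors
#' @export
setGeneric("sampleFractions", function(x) standardGeneric("sampleFractions"))

#' @rdname FractionExpression-accessors
#' @export
setGeneric("meanTPM", function(x, fraction) standardGeneric("meanTPM"))
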