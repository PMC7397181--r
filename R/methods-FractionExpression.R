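#' Accessors for FractionExpression
#'
#' \code{tpm} returns the TPM matrix; \code{sampleFractions} the per-sample
#' fraction labels; \code{meanTPM} the per-transcript mean TPM across the
#' replicates of one fraction.
#'
#' @param x A \linkS4class{FractionExpression}.
#' @param fraction \code{"cytoplasm"} or \code{"nucleus"}.
#' @name FractionExpression-accessors
NULL

#' @rdname FractionExpression-accessors
#' @export
setMethod("tpm", "FractionExpression", function(x) assay(x, "TPM"))

#' @rdname FractionExpression-accessors
#' @export
setMethod("sampleFractions", "FractionExpression", function(x) {
  out <- as.character(colData(x)$fraction)
  names(out) <- colnames(x)
  out
})

#' @rdname FractionExpression-accessors
#' @export
setMethod("meanTPM", "FractionExpression", function(x, fraction) {
  fraction <- match.arg(fraction, c("cytoplasm", "nucleus"))
  m <- assay(x, "TPM")[, colData(x)$fraction == fraction, drop = FALSE]
  rowMeans(m)
})

setMethod("show", "FractionExpression", function(object) {
  cd <- colData(object)
  cat("FractionExpression:", nrow(object), "transcripts x", ncol(object),
      "samples\n")
  cat("  cytoplasm replicates:", sum(cd$fraction == "cytoplasm"),
      "| nucleus replicates:", sum(cd$fraction == "nucleus"), "\n")
})

#' Swap the fraction labels of every sample
#'
#' Utility for label-exchange invariance checks: cytoplasm samples become
#' nucleus samples and vice versa.
#'
#' @param x A \linkS4class{FractionExpression}.
#' @return A \linkS4class{FractionExpression} with swapped labels.
#' @export
swapFractions <- function(x) {
  f <- sampleFractions(x)
  FractionExpression(tpm(x),
                     ifelse(f == "cytoplasm", "nucleus", "cytoplasm"),
                     colData(x)$replicate)
}
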