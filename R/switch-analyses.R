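#' Length-ratio categories of switch pairs
#'
#' For each switch pair the log2 ratio of the cytoplasmic over the nuclear
#' transcript length (summed exon length) is computed and categorized:
#' positive (ratio > 1), negative (ratio < -1), neutral (otherwise). A
#' two-sided exact binomial test compares the positive vs negative counts
#' against p = 0.5.
#'
#' @param pairs data.frame from [callSwitches()].
#' @param ts A \linkS4class{TranscriptSet}.
#' @return list with \code{pairs} (input plus \code{length_ratio_log2} and
#'   \code{category}), \code{counts} (named vector) and \code{test}
#'   (binomial test-result row).
#' @export
classifyLengthRatio <- function(pairs, ts) {
  lens <- txLengths(ts)
  lc <- lens[pairs$tc_id]
  ln <- lens[pairs$tn_id]
  if (any(lc == 0 | ln == 0)) stop("zero-length transcript in annotation")
  ratio <- log2(lc / ln)
  category <- ifelse(ratio > 1, "positive",
                     ifelse(ratio < -1, "negative", "neutral"))
  pairs$length_ratio_log2 <- unname(ratio)
  pairs$category <- unname(category)
  counts <- c(positive = sum(category == "positive"),
              negative = sum(category == "negative"),
              neutral = sum(category == "neutral"))
  test <- if (counts["positive"] + counts["negative"] > 0)
    binomialTest(unname(counts["positive"]),
                 unname(counts["positive"] + counts["negative"]), 0.5)
  else NULL
  list(pairs = pairs, counts = counts, test = test)
}

#' Compare exon counts of cytoplasmic vs nuclear switch transcripts
#'
#' Mood's median test on the exon numbers (splicing frequency) of Tc vs Tn
#' members within one length-ratio category.
#'
#' @param pairs data.frame with a \code{category} column (see
#'   [classifyLengthRatio()]).
#' @param ts A \linkS4class{TranscriptSet}.
#' @param category \code{"positive"}, \code{"negative"} or \code{"neutral"}.
#' @return test-result data.frame (x = Tc exon counts, y = Tn exon counts).
#' @export
compareExonCounts <- function(pairs, ts, category = "positive") {
  if (!"category" %in% colnames(pairs))
    stop("pairs lack a category column; run classifyLengthRatio() first")
  sel <- pairs[pairs$category == category, , drop = FALSE]
  if (nrow(sel) < 2) stop("fewer than 2 pairs in category ", category)
  ec <- exonCounts(ts)
  moodsMedianTest(as.numeric(ec[sel$tc_id]), as.numeric(ec[sel$tn_id]))
}

#' Compare deltaTU of mono-exonic vs multi-exonic switch transcripts
#'
#' Welch two-tailed t-test on deltaTU of the transcripts that participate in
#' switch pairs, split by whether they are mono-exonic (unspliced) or
#' multi-exonic (spliced).
#'
#' @param usage result of [computeUsage()] (p-values not required).
#' @param ts A \linkS4class{TranscriptSet}.
#' @param pairs data.frame from [callSwitches()]; membership defines the
#'   tested transcripts.
#' @return test-result data.frame (x = mono-exonic, y = multi-exonic).
#' @export
compareMonoMulti <- function(usage, ts, pairs) {
  members <- unique(c(pairs$tc_id, pairs$tn_id))
  u <- usage[usage$transcript_id %in% members, , drop = FALSE]
  ec <- exonCounts(ts)[u$transcript_id]
  mono <- u$delta_tu[ec == 1]
  multi <- u$delta_tu[ec > 1]
  if (length(mono) < 2 || length(multi) < 2)
    stop("need at least 2 mono-exonic and 2 multi-exonic transcripts")
  welchTTest(mono, multi)
}

#' Compare deltaTU of coding vs noncoding transcripts
#'
#' Mood's median test on deltaTU between coding and noncoding transcripts.
#'
#' @param usage result of [computeUsage()].
#' @param ts A \linkS4class{TranscriptSet}.
#' @return test-result data.frame (x = coding, y = noncoding), or NULL with
#'   a warning when one biotype is absent.
#' @export
compareBiotype <- function(usage, ts) {
  bt <- txBiotype(ts)[usage$transcript_id]
  coding <- usage$delta_tu[bt == "coding"]
  noncod <- usage$delta_tu[bt == "noncoding"]
  if (length(coding) == 0 || length(noncod) == 0) {
    warning("only one biotype present; comparison skipped")
    return(NULL)
  }
  moodsMedianTest(coding, noncod)
}

#' Per-transcript NMD sensitivity
#'
#' Sensitivity to nonsense-mediated decay, defined as the log2 fold-change
#' of transcript expression after knockdown of an NMD factor:
#' log2((TPM_kd + c) / (TPM_ctrl + c)) with pseudo-count c (default 0.01
#' TPM). Expression is averaged over all samples of each table.
#'
#' @param fe_ctrl,fe_kd \linkS4class{FractionExpression} tables over the
#'   same transcripts (control and knockdown).
#' @param pseudo pseudo-count in TPM.
#' @return named numeric vector of sensitivities.
#' @export
nmdSensitivity <- function(fe_ctrl, fe_kd, pseudo = 0.01) {
  if (!setequal(rownames(fe_ctrl), rownames(fe_kd)))
    stop("control and knockdown tables cover different transcripts")
  ids <- rownames(fe_ctrl)
  ctrl <- rowMeans(tpm(fe_ctrl))[ids]
  kd <- rowMeans(tpm(fe_kd))[ids]
  out <- log2((kd + pseudo) / (ctrl + pseudo))
  names(out) <- ids
  out
}

#' Compare NMD sensitivity between cytoplasmic and nuclear switch members
#'
#' Mood's median test of NMD sensitivity between Tc and Tn transcripts; a
#' non-significant result argues that differential decay does not explain
#' the switches.
#'
#' @param sens named vector from [nmdSensitivity()].
#' @param pairs data.frame from [callSwitches()].
#' @return test-result data.frame (x = Tc, y = Tn).
#' @export
compareNMD <- function(sens, pairs) {
  miss <- setdiff(c(pairs$tc_id, pairs$tn_id), names(sens))
  if (length(miss)) stop("sensitivity missing for some switch transcripts")
  moodsMedianTest(as.numeric(sens[pairs$tc_id]),
                  as.numeric(sens[pairs$tn_id]))
}
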