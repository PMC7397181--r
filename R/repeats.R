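#' Repeat-class overlap enrichment
#'
#' For each repeat class, the fraction of intronic bases overlapped by
#' repeats of that class is computed in the nuclear-RI set and the
#' background set; the ratio of fractions measures enrichment, and the
#' density difference is assessed by permutation of intron set labels
#' (set sizes preserved), BH-corrected across classes.
#'
#' @param repeats GRanges with a \code{repeat_class} column (see
#'   [readBED()]).
#' @param nuclear_introns,background_introns GRanges of introns.
#' @param n_shuffles number of label permutations, default 200.
#' @param seed RNG seed.
#' @return data.frame feature_id (class), density_target,
#'   density_background (overlapped-base fractions), ratio, p_value,
#'   q_value.
#' @export
repeatEnrichment <- function(repeats, nuclear_introns, background_introns,
                             n_shuffles = 200, seed = 1L) {
  # fixtures routinely place intron sets on disjoint chromosomes; the
  # seqlevel-merge warning from c() is expected there
  introns <- suppressWarnings(
    c(GenomicRanges::granges(nuclear_introns),
      GenomicRanges::granges(background_introns)))
  is_target <- c(rep(TRUE, length(nuclear_introns)),
                 rep(FALSE, length(background_introns)))
  classes <- sort(unique(as.character(repeats$repeat_class)))
  if (length(classes) == 0) classes <- "none"
  qty <- matrix(0, length(introns), length(classes),
                dimnames = list(NULL, classes))
  for (cl in classes) {
    rep_cl <- GenomicRanges::reduce(
      repeats[as.character(repeats$repeat_class) == cl])
    if (length(rep_cl) == 0) next
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(introns, rep_cl, ignore.strand = TRUE))
    if (length(ov) == 0) next
    w <- width(IRanges::pintersect(
      IRanges::ranges(introns)[S4Vectors::queryHits(ov)],
      IRanges::ranges(rep_cl)[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    qty[as.integer(names(agg)), cl] <- as.numeric(agg)
  }
  out <- .permutationEnrichment(qty, width(introns), is_target,
                                n_shuffles, seed)
  out$q_value <- bhFDR(out$p_value)
  out
}

#' Total bases of a set of intervals overlapped by another set
#'
#' Exact interval arithmetic helper (invariant under splitting intervals
#' into adjacent pieces).
#'
#' @param query,subject GRanges.
#' @return integer total overlapped bases of \code{query}.
#' @export
overlappedBases <- function(query, subject) {
  subject <- GenomicRanges::reduce(GenomicRanges::granges(subject))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE))
  if (length(ov) == 0) return(0L)
  sum(width(IRanges::pintersect(
    IRanges::ranges(query)[S4Vectors::queryHits(ov)],
    IRanges::ranges(subject)[S4Vectors::subjectHits(ov)])))
}
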