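#' Base-pairing probabilities from a uniform-energy partition function
#'
#' Boltzmann ensemble over all nested secondary structures with
#' Watson-Crick and GU-wobble pairs, a minimum hairpin loop of
#' \code{min_hairpin} unpaired bases and one uniform energy per pair
#' (Boltzmann weight \code{pair_weight}, default exp(2), i.e. about 2RT
#' per stacked pair so that designed helices clearly dominate the
#' ensemble). The stem
#' (pairedness) probability of a base is the sum over partners of its pair
#' probabilities; the higher the mean stem probability, the more stable the
#' ensemble. This is a deliberately simple pairing model: the analysis only
#' uses the mean stem probability as a relative statistic between intron
#' sets.
#'
#' Sequences longer than \code{cap} nucleotides are scored on a centred
#' window of \code{cap} bases (reported via attribute \code{"windowed"}).
#'
#' @param sequence character, RNAString or DNAString (T is read as U).
#' @param pair_weight Boltzmann weight per pair, default exp(2).
#' @param min_hairpin minimum hairpin loop length, default 3.
#' @param cap maximum folded length, default 2000.
#' @return list with \code{prob} (per-base pairedness vector), \code{mean}
#'   (its mean) and \code{pair_matrix} (symmetric pair-probability matrix).
#' @export
stemProbabilities <- function(sequence, pair_weight = exp(2),
                              min_hairpin = 3, cap = 2000) {
  codes <- .rnaCodes(sequence, cap)
  P <- .pairProbMatrixCpp(attr(codes, "window"), pair_weight,
                          as.integer(min_hairpin))
  prob <- pmin(rowSums(P), 1)
  out <- list(prob = prob, mean = if (length(prob)) mean(prob) else 0,
              pair_matrix = P)
  attr(out, "windowed") <- attr(codes, "windowed")
  out
}

#' Mean stem probability of a sequence
#'
#' Equals \code{mean(stemProbabilities(x)$prob)} but is computed in a
#' single inside pass via the derivative of the log partition function
#' (mean pairedness = 2 E[pairs] / n), which is what the intron-set
#' comparisons use.
#'
#' @inheritParams stemProbabilities
#' @return numeric scalar in [0, 1].
#' @export
meanStemProbability <- function(sequence, pair_weight = exp(2),
                                min_hairpin = 3, cap = 2000) {
  codes <- .rnaCodes(sequence, cap)
  .meanPairednessCpp(attr(codes, "window"), pair_weight,
                     as.integer(min_hairpin))
}

.rnaCodes <- function(sequence, cap) {
  s <- toupper(as.character(sequence))
  s <- chartr("T", "U", s)
  v <- strsplit(s, "")[[1]]
  codes <- match(v, c("A", "C", "G", "U")) - 1L
  if (anyNA(codes))
    stop("non-ACGU symbol in sequence: ",
         paste(unique(v[is.na(codes)]), collapse = ""))
  windowed <- FALSE
  if (length(codes) > cap) {
    off <- (length(codes) - cap) %/% 2
    codes_w <- codes[(off + 1):(off + cap)]
    windowed <- TRUE
  } else codes_w <- codes
  out <- codes
  attr(out, "window") <- codes_w
  attr(out, "windowed") <- windowed
  out
}
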