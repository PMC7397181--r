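#' PWM motif scanning with an exact score-quantile threshold
#'
#' Sequences are scored on the sense (transcribed) strand with log2-odds
#' against a uniform background. The hit threshold is the exact upper
#' quantile of the PWM's score distribution over all k-mers, computed by
#' dynamic programming over positions: a position scores >= t where t is
#' the smallest support value with P(score >= t) <= 1 - threshold_quantile.
#'
#' @name motif-scanning
NULL

# exact distribution of the log-odds score of a random uniform k-mer:
# data.frame(score, prob), sorted by score. Positions contribute one of 4
# values with probability 1/4 each; the support is collapsed by rounding
# so it stays far below 4^k for real PWMs.
.pwmScoreDistribution <- function(logodds) {
  dist <- c(`0` = 1)
  for (j in seq_len(ncol(logodds))) {
    vals <- outer(as.numeric(names(dist)), logodds[, j], "+")
    prb <- rep(dist / 4, times = 4)
    key <- as.character(round(as.vector(vals), 9))
    dist <- vapply(split(as.vector(prb), key), sum, numeric(1))
  }
  score <- as.numeric(names(dist))
  o <- order(score)
  data.frame(score = score[o], prob = unname(dist[o]))
}

.pwmLogOdds <- function(pwm) log2(pwm / 0.25)

#' Scan one sequence with one PWM
#'
#' @param pwm 4 x k probability matrix, rows A, C, G, U (see [readPWMs()]).
#' @param sequence character/RNAString in the RNA alphabet (T accepted and
#'   read as U).
#' @param threshold_quantile exact score quantile defining a hit, default
#'   0.95.
#' @return data.frame with position (1-based start on the sense strand) and
#'   score for each hit; zero rows if the sequence is shorter than the
#'   motif.
#' @export
scanPWM <- function(pwm, sequence, threshold_quantile = 0.95) {
  lo <- .pwmLogOdds(pwm)
  k <- ncol(lo)
  s <- chartr("T", "U", toupper(as.character(sequence)))
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
  if (anyNA(codes)) stop("non-ACGU symbol in sequence")
  n <- length(codes)
  if (n < k)
    return(data.frame(position = integer(0), score = numeric(0)))
  dist <- .pwmScoreDistribution(lo)
  upper <- rev(cumsum(rev(dist$prob)))   # P(score >= support value)
  ok <- which(upper <= 1 - threshold_quantile)
  thr <- if (length(ok)) dist$score[min(ok)] else Inf
  scores <- numeric(n - k + 1)
  for (j in seq_len(k))
    scores <- scores + lo[cbind(codes[j:(j + n - k)], j)]
  hit <- which(scores >= thr - 1e-9)
  data.frame(position = hit, score = scores[hit])
}

# hit counts for each pwm x sequence; rows sequences, cols motifs
.hitCountMatrix <- function(pwms, seqs, threshold_quantile) {
  seqs <- as.character(seqs)
  out <- matrix(0L, length(seqs), length(pwms),
                dimnames = list(names(seqs), names(pwms)))
  for (m in seq_along(pwms)) {
    lo <- .pwmLogOdds(pwms[[m]])
    dist <- .pwmScoreDistribution(lo)
    upper <- rev(cumsum(rev(dist$prob)))
    ok <- which(upper <= 1 - threshold_quantile)
    thr <- if (length(ok)) dist$score[min(ok)] else Inf
    k <- ncol(lo)
    for (i in seq_along(seqs)) {
      codes <- match(strsplit(chartr("T", "U", toupper(seqs[i])),
                              "")[[1]], c("A", "C", "G", "U"))
      n <- length(codes)
      if (n < k || anyNA(codes)) next
      sc <- numeric(n - k + 1)
      for (j in seq_len(k))
        sc <- sc + lo[cbind(codes[j:(j + n - k)], j)]
      out[i, m] <- sum(sc >= thr - 1e-9)
    }
  }
  out
}

# shared permutation machinery: per-unit quantities for target/background
# sets; statistic = density difference; two-sided permutation p with
# add-one correction. qty: units x features matrix; len: per-unit size
# (kb or bases).
.permutationEnrichment <- function(qty, len, is_target, n_shuffles, seed) {
  dens <- function(sel) colSums(qty[sel, , drop = FALSE]) /
    max(sum(len[sel]), .Machine$double.eps)
  dt <- dens(is_target)
  db <- dens(!is_target)
  obs <- dt - db
  set.seed(seed)
  n_t <- sum(is_target)
  exceed <- rep(0L, ncol(qty))
  for (b in seq_len(n_shuffles)) {
    perm <- sample(length(len))
    sel <- logical(length(len))
    sel[perm[seq_len(n_t)]] <- TRUE
    d <- dens(sel) - dens(!sel)
    exceed <- exceed + (abs(d) >= abs(obs) - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_shuffles)
  data.frame(feature_id = colnames(qty), density_target = dt,
             density_background = db,
             ratio = ifelse(db > 0, dt / db, NA_real_),
             p_value = p, stringsAsFactors = FALSE, row.names = NULL)
}

#' RBP-motif enrichment in nuclear RIs vs background RIs
#'
#' Scans every PWM over both intron sets (sense strand), computes hit
#' densities per kilobase, and assesses the density difference per motif by
#' permutation of the set labels (set sizes preserved), with BH correction
#' across motifs.
#'
#' @param pwms named list of PWMs (see [readPWMs()]).
#' @param nuclear_seqs,background_seqs RNAStringSet (or character vectors)
#'   of intron sequences.
#' @param n_shuffles number of label permutations, default 200.
#' @param seed RNG seed for the permutations.
#' @param threshold_quantile hit threshold quantile, default 0.95.
#' @return data.frame with feature_id (motif), rbp_name, densities (hits
#'   per kb), ratio, p_value, q_value.
#' @export
rbpEnrichment <- function(pwms, nuclear_seqs, background_seqs,
                          n_shuffles = 200, seed = 1L,
                          threshold_quantile = 0.95) {
  if (length(nuclear_seqs) == 0 || length(background_seqs) == 0)
    stop("both intron sets must be non-empty")
  seqs <- c(as.character(nuclear_seqs), as.character(background_seqs))
  is_target <- c(rep(TRUE, length(nuclear_seqs)),
                 rep(FALSE, length(background_seqs)))
  hits <- .hitCountMatrix(pwms, seqs, threshold_quantile)
  len_kb <- nchar(seqs) / 1000
  out <- .permutationEnrichment(hits, len_kb, is_target, n_shuffles, seed)
  out$rbp_name <- vapply(pwms[out$feature_id], function(m)
    attr(m, "rbp_name") %||% "", character(1))
  out$q_value <- bhFDR(out$p_value)
  out[, c("feature_id", "rbp_name", "density_target",
          "density_background", "ratio", "p_value", "q_value")]
}

#' Features consistently enriched across result sets
#'
#' Joins enrichment tables from several datasets (e.g. cell lines) and
#' reports features significant (q below \code{alpha}, ratio above 1) in at
#' least \code{min_frac} of them; under-represented features (ratio below
#' 1) are reported symmetrically.
#'
#' @param tables list of data.frames from [rbpEnrichment()] or
#'   [repeatEnrichment()].
#' @param min_frac minimum fraction of datasets, default 0.8.
#' @param alpha per-dataset q-value cutoff, default 0.05.
#' @return data.frame feature_id, n_datasets, n_enriched, n_depleted,
#'   consistent ("enriched"/"depleted"/"none").
#' @export
consistencyReport <- function(tables, min_frac = 0.8, alpha = 0.05) {
  feats <- unique(unlist(lapply(tables, `[[`, "feature_id")))
  rows <- lapply(feats, function(f) {
    enr <- dep <- 0L
    for (tb in tables) {
      r <- tb[tb$feature_id == f, , drop = FALSE]
      if (nrow(r) == 0) next
      qcol <- if ("q_value" %in% colnames(r)) r$q_value else r$p_value
      if (!is.na(qcol[1]) && qcol[1] < alpha && !is.na(r$ratio[1])) {
        if (r$ratio[1] > 1) enr <- enr + 1L
        if (r$ratio[1] < 1) dep <- dep + 1L
      }
    }
    n <- length(tables)
    data.frame(feature_id = f, n_datasets = n, n_enriched = enr,
               n_depleted = dep,
               consistent = if (enr >= min_frac * n) "enriched"
               else if (dep >= min_frac * n) "depleted" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
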