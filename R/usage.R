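#' Transcript usage and its change between fractions
#'
#' Transcript usage (TU) is a transcript's share of its gene's total TPM,
#' computed per fraction from replicate-mean TPM; gene TPM is the sum of the
#' gene's transcript TPMs, so TU sums to 1 per gene and fraction by
#' construction. deltaTU = TU_cytoplasm - TU_nucleus: positive values mark
#' cytoplasm-enriched isoforms, negative values nucleus-enriched ones. Genes
#' whose total TPM falls below \code{tpm_floor} in either fraction are
#' excluded (usage is unreliable at low expression); the number excluded is
#' attached as the \code{"excluded_genes"} attribute.
#'
#' @param fe A \linkS4class{FractionExpression}.
#' @param ts A \linkS4class{TranscriptSet}; every expression row must be
#'   annotated.
#' @param tpm_floor minimum gene TPM (replicate mean) required in both
#'   fractions, default 1.
#' @return data.frame with columns transcript_id, gene_id, tu_cyto, tu_nuc,
#'   delta_tu, p_value (NA until [empiricalPvalues()] fills it).
#' @export
computeUsage <- function(fe, ts, tpm_floor = 1) {
  ids <- rownames(fe)
  miss <- setdiff(ids, transcriptIds(ts))
  if (length(miss))
    stop("transcripts not in annotation: ", paste(utils::head(miss, 3),
                                                  collapse = ", "))
  gene <- unname(geneIds(ts)[ids])
  mc <- meanTPM(fe, "cytoplasm")
  mn <- meanTPM(fe, "nucleus")
  gc <- tapply(mc, gene, sum)[gene]
  gn <- tapply(mn, gene, sum)[gene]
  keep <- gc >= tpm_floor & gn >= tpm_floor
  out <- data.frame(transcript_id = ids[keep], gene_id = gene[keep],
                    tu_cyto = (mc / gc)[keep], tu_nuc = (mn / gn)[keep],
                    p_value = rep(NA_real_, sum(keep)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$delta_tu <- out$tu_cyto - out$tu_nuc
  out <- out[, c("transcript_id", "gene_id", "tu_cyto", "tu_nuc",
                 "delta_tu", "p_value")]
  attr(out, "excluded_genes") <- length(unique(gene[!keep]))
  out
}

# Empirical null machinery shared by deltaTU and deltaPSI significance.
# obs: observed statistic per unit; rep_stats: unit x sample matrix of
# per-replicate statistics; expr_level: pooling covariate (log10 TPM);
# fraction labels per sample. The null pools within-fraction replicate-pair
# differences across units of similar expression (quantile bins) and is
# rescaled by sqrt((1/n_c + 1/n_n)/2): a replicate-pair difference has
# variance 2*sigma^2 while the observed mean-vs-mean statistic has variance
# sigma^2*(1/n_c + 1/n_n), and matching scales is what makes null p-values
# uniform.
.empiricalP <- function(obs, rep_stats, expr_level, fraction, n_bins = 5) {
  stopifnot(length(obs) == nrow(rep_stats))
  fr_levels <- c("cytoplasm", "nucleus")
  n_c <- sum(fraction == "cytoplasm")
  n_n <- sum(fraction == "nucleus")
  if (n_c < 2 || n_n < 2)
    stop("empirical significance requires at least 2 replicates per fraction")
  scale_fac <- sqrt((1 / n_c + 1 / n_n) / 2)
  nulls <- list()
  for (fr in fr_levels) {
    cols <- which(fraction == fr)
    prs <- utils::combn(cols, 2)
    for (p in seq_len(ncol(prs)))
      nulls[[length(nulls) + 1L]] <-
        rep_stats[, prs[1, p]] - rep_stats[, prs[2, p]]
  }
  null_mat <- do.call(cbind, nulls) * scale_fac   # unit x pair
  # expression bins (quantile cut; collapse if too few distinct levels)
  qs <- unique(stats::quantile(expr_level, probs = seq(0, 1, length.out =
                                                         n_bins + 1),
                               na.rm = TRUE))
  if (length(qs) < 3) {
    bin <- rep(1L, length(expr_level))
  } else {
    bin <- cut(expr_level, qs, include.lowest = TRUE, labels = FALSE)
  }
  p_out <- rep(NA_real_, length(obs))
  for (b in unique(bin)) {
    in_bin <- which(bin == b)
    nv <- abs(as.vector(null_mat[in_bin, , drop = FALSE]))
    nv <- nv[!is.na(nv)]
    if (length(nv) == 0) next
    nv <- sort(nv)
    ob <- abs(obs[in_bin])
    # #{|null| >= |obs|} via binary search on the sorted null
    ge <- length(nv) - findInterval(ob - 1e-12, nv)
    p_out[in_bin] <- (1 + ge) / (1 + length(nv))
  }
  p_out
}

#' Empirical p-values for deltaTU
#'
#' Significance of each transcript's usage change, in the spirit of
#' SUPPA2's empirical test: the null distribution is built from
#' between-replicate deltaTU values within each fraction (all replicate
#' pairs, both fractions), pooled across transcripts of similar gene
#' expression (quantile bins of log10 gene TPM) and rescaled to the sampling
#' scale of the replicate-mean statistic. p = (1 + #{|null| >= |obs|}) /
#' (1 + N_null). The procedure is deterministic; \code{seed} is accepted for
#' interface symmetry and reserved for null subsampling.
#'
#' @param usage result of [computeUsage()].
#' @param fe the \linkS4class{FractionExpression} the usage was computed
#'   from (>= 2 replicates per fraction).
#' @param n_bins number of gene-expression bins, default 5.
#' @param seed unused at present (no subsampling); kept for reproducibility
#'   contracts.
#' @return \code{usage} with \code{p_value} filled in.
#' @export
empiricalPvalues <- function(usage, fe, n_bins = 5, seed = 1L) {
  ids <- usage$transcript_id
  m <- tpm(fe)[ids, , drop = FALSE]
  gene <- usage$gene_id
  fraction <- sampleFractions(fe)
  # per-replicate TU: transcript TPM / gene TPM within each sample
  gsum <- rowsum(m, gene)[gene, , drop = FALSE]
  tu_rep <- m / gsum
  tu_rep[gsum == 0] <- NA
  expr_level <- log10(pmax(rowMeans(gsum), 1e-9))
  usage$p_value <- .empiricalP(usage$delta_tu, tu_rep, expr_level, fraction,
                               n_bins = n_bins)
  usage
}

#' Call transcript switch pairs
#'
#' Per gene, the cytoplasmic transcript Tc is the one maximizing deltaTU
#' among transcripts with deltaTU > threshold and p < alpha, and the nuclear
#' transcript Tn minimizes deltaTU among those with deltaTU < -threshold and
#' p < alpha. A switch pair is emitted only when both exist. Ties are broken
#' by lexicographic transcript id.
#'
#' @param usage result of [empiricalPvalues()].
#' @param threshold minimum |deltaTU|, default 0.2.
#' @param alpha significance level, default 0.05.
#' @return data.frame with gene_id, tc_id, tn_id, delta_tu_c, delta_tu_n,
#'   p_c, p_n.
#' @export
callSwitches <- function(usage, threshold = 0.2, alpha = 0.05) {
  if (all(is.na(usage$p_value)))
    stop("usage has no p-values; run empiricalPvalues() first")
  ok <- !is.na(usage$p_value)
  u <- usage[ok, , drop = FALSE]
  # deterministic tie-break: sort by (delta, transcript_id)
  pick <- function(df, positive) {
    cand <- if (positive)
      df[df$delta_tu > threshold & df$p_value < alpha, , drop = FALSE]
    else df[df$delta_tu < -threshold & df$p_value < alpha, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    o <- order(if (positive) -cand$delta_tu else cand$delta_tu,
               cand$transcript_id)
    cand[o[1], , drop = FALSE]
  }
  rows <- lapply(split(u, u$gene_id), function(df) {
    tc <- pick(df, TRUE)
    tn <- pick(df, FALSE)
    if (is.null(tc) || is.null(tn)) return(NULL)
    data.frame(gene_id = df$gene_id[1], tc_id = tc$transcript_id,
               tn_id = tn$transcript_id, delta_tu_c = tc$delta_tu,
               delta_tu_n = tn$delta_tu, p_c = tc$p_value, p_n = tn$p_value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(gene_id = character(0), tc_id = character(0),
                      tn_id = character(0), delta_tu_c = numeric(0),
                      delta_tu_n = numeric(0), p_c = numeric(0),
                      p_n = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes called as switching in at least k result sets
#'
#' Convenience join across per-dataset switch tables (e.g. different cell
#' lines): report genes detected in at least \code{k} of them.
#'
#' @param switch_tables list of data.frames from [callSwitches()].
#' @param k minimum number of datasets, default 5.
#' @return data.frame gene_id, n_datasets.
#' @export
sharedSwitchingGenes <- function(switch_tables, k = 5) {
  tab <- table(unlist(lapply(switch_tables, function(s) unique(s$gene_id))))
  out <- data.frame(gene_id = names(tab), n_datasets = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[out$n_datasets >= k, , drop = FALSE]
}
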