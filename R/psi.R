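#' Event inclusion levels (PSI) and their change between fractions
#'
#' For each event, PSI = sum of inclusion-transcript TPM / (inclusion +
#' exclusion TPM), computed per fraction on replicate-mean TPM. deltaPSI =
#' PSI_cytoplasm - PSI_nucleus, so negative values mark event forms
#' enriched in the nucleus. Events whose total (inclusion + exclusion) TPM
#' falls below \code{tpm_floor} in either fraction are skipped; the number
#' skipped is attached as attribute \code{"skipped"}.
#'
#' @param events data.frame from [extractEvents()].
#' @param fe A \linkS4class{FractionExpression}.
#' @param tpm_floor minimum event TPM per fraction, default 1.
#' @return data.frame with event_id, gene_id, kind, psi_cyto, psi_nuc,
#'   delta_psi, p_value (NA until [psiPvalues()]).
#' @export
computeDeltaPsi <- function(events, fe, tpm_floor = 1) {
  if (nrow(events) == 0)
    return(structure(data.frame(event_id = character(0),
                                gene_id = character(0), kind = character(0),
                                psi_cyto = numeric(0), psi_nuc = numeric(0),
                                delta_psi = numeric(0), p_value = numeric(0),
                                stringsAsFactors = FALSE), skipped = 0L))
  ids <- rownames(fe)
  mc <- meanTPM(fe, "cytoplasm")
  mn <- meanTPM(fe, "nucleus")
  sumTPM <- function(txs, v) sum(v[intersect(txs, ids)])
  rows <- lapply(seq_len(nrow(events)), function(i) {
    incl <- events$inclusion[[i]]; excl <- events$exclusion[[i]]
    ic <- sumTPM(incl, mc); ec <- sumTPM(excl, mc)
    inn <- sumTPM(incl, mn); en <- sumTPM(excl, mn)
    if (ic + ec < tpm_floor || inn + en < tpm_floor) return(NULL)
    psi_c <- ic / (ic + ec)
    psi_n <- inn / (inn + en)
    data.frame(event_id = events$event_id[i], gene_id = events$gene_id[i],
               kind = events$kind[i], psi_cyto = psi_c, psi_nuc = psi_n,
               delta_psi = psi_c - psi_n, p_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(event_id = character(0), gene_id = character(0),
               kind = character(0), psi_cyto = numeric(0),
               psi_nuc = numeric(0), delta_psi = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(!keep)
  out
}

#' PSI of one fraction for a set of events
#'
#' @param events data.frame from [extractEvents()].
#' @param fe A \linkS4class{FractionExpression}.
#' @param fraction \code{"cytoplasm"} or \code{"nucleus"}.
#' @return named numeric vector of PSI values (NA where the event's total
#'   TPM is zero).
#' @export
computePsi <- function(events, fe, fraction) {
  mv <- meanTPM(fe, fraction)
  ids <- rownames(fe)
  out <- vapply(seq_len(nrow(events)), function(i) {
    ic <- sum(mv[intersect(events$inclusion[[i]], ids)])
    ec <- sum(mv[intersect(events$exclusion[[i]], ids)])
    if (ic + ec == 0) return(NA_real_)
    ic / (ic + ec)
  }, numeric(1))
  names(out) <- events$event_id
  out
}

#' Empirical p-values for deltaPSI
#'
#' Same between-replicate empirical scheme as [empiricalPvalues()]: the null
#' pools within-fraction replicate-pair PSI differences across events of
#' similar total expression (quantile bins of log10 event TPM), rescaled to
#' the replicate-mean sampling scale.
#'
#' @param psi result of [computeDeltaPsi()].
#' @param events the events the PSI table was computed from.
#' @param fe the \linkS4class{FractionExpression} (>= 2 replicates per
#'   fraction).
#' @param n_bins number of expression bins, default 5.
#' @param seed reserved (the procedure is deterministic).
#' @return \code{psi} with \code{p_value} filled in.
#' @export
psiPvalues <- function(psi, events, fe, n_bins = 5, seed = 1L) {
  if (nrow(psi) == 0) return(psi)
  ev <- events[match(psi$event_id, events$event_id), , drop = FALSE]
  m <- tpm(fe)
  ids <- rownames(fe)
  n_ev <- nrow(ev)
  psi_rep <- matrix(NA_real_, n_ev, ncol(m))
  tot_rep <- matrix(0, n_ev, ncol(m))
  for (i in seq_len(n_ev)) {
    incl <- intersect(ev$inclusion[[i]], ids)
    excl <- intersect(ev$exclusion[[i]], ids)
    ic <- colSums(m[incl, , drop = FALSE])
    ec <- colSums(m[excl, , drop = FALSE])
    tot <- ic + ec
    psi_rep[i, ] <- ifelse(tot > 0, ic / tot, NA_real_)
    tot_rep[i, ] <- tot
  }
  expr_level <- log10(pmax(rowMeans(tot_rep), 1e-9))
  psi$p_value <- .empiricalP(psi$delta_psi, psi_rep, expr_level,
                             sampleFractions(fe), n_bins = n_bins)
  psi
}

#' Select nucleus-enriched retained introns
#'
#' Nuclear RIs are RI events with deltaPSI < 0 and p < alpha; the full RI
#' set is retained as the comparison background.
#'
#' @param psi result of [psiPvalues()].
#' @param alpha significance level, default 0.05.
#' @return list with \code{nuclear} (selected RI rows) and \code{all_ri}
#'   (every quantified RI event).
#' @export
selectNuclearRIs <- function(psi, alpha = 0.05) {
  ri <- psi[psi$kind == "RI", , drop = FALSE]
  nuclear <- ri[!is.na(ri$p_value) & ri$delta_psi < 0 &
                  ri$p_value < alpha, , drop = FALSE]
  list(nuclear = nuclear, all_ri = ri)
}

#' Per-kind deltaPSI distribution summary
#'
#' For each event kind: number of events, median deltaPSI, and Mood's
#' median test of that kind against all other kinds pooled. Kinds with
#' fewer than 5 events are flagged low-power.
#'
#' @param psi result of [computeDeltaPsi()] (p-values not required).
#' @return data.frame kind, n, median_delta_psi, p_value, low_power.
#' @export
psiByKind <- function(psi) {
  kinds <- sort(unique(psi$kind))
  rows <- lapply(kinds, function(k) {
    x <- psi$delta_psi[psi$kind == k]
    y <- psi$delta_psi[psi$kind != k]
    p <- if (length(x) >= 2 && length(y) >= 2)
      moodsMedianTest(x, y)$p_value else NA_real_
    data.frame(kind = k, n = length(x),
               median_delta_psi = stats::median(x), p_value = p,
               low_power = length(x) < 5, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
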