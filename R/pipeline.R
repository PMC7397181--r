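#' Read an analysis configuration file
#'
#' YAML key-value schema: \code{gtf}, \code{expression}, \code{samples}
#' (TSV with sample_id, fraction, replicate), optional \code{fasta},
#' \code{bed}, \code{pwms}, \code{out_dir}, and optional numeric overrides
#' \code{tpm_floor}, \code{delta_tu_threshold}, \code{alpha},
#' \code{min_tx_length} (optional transcript-length filter, off by
#' default).
#'
#' @param path YAML file.
#' @return named list of settings with defaults filled in.
#' @export
readAnalysisConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(tpm_floor = 1, delta_tu_threshold = 0.2, alpha = 0.05,
                   min_tx_length = 0, out_dir = ".")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("gtf", "expression", "samples"))
    if (is.null(cfg[[nm]])) stop("config misses required key: ", nm)
  cfg
}

#' Run the localization analysis end to end
#'
#' Reads annotation and expression, computes usage and empirical
#' significance, calls switch pairs and their length/exon-count
#' comparisons, extracts events, quantifies PSI/deltaPSI and selects
#' nuclear RIs; when a genome is supplied, also profiles the RI introns
#' (length, stem probability, dinucleotides, boundaries) and, when PWMs or
#' repeats are supplied, their enrichments. Tables are written to
#' \code{out_dir} via [writeResults()].
#'
#' @param config list from [readAnalysisConfig()] (or an equivalent list).
#' @return named list of result tables, invisibly.
#' @export
runLocalizationAnalysis <- function(config) {
  ts <- readGTF(config$gtf)
  meta <- utils::read.delim(config$samples, stringsAsFactors = FALSE)
  fe <- readExpression(config$expression, meta)
  if (config$min_tx_length > 0) {
    keep <- txLengths(ts) >= config$min_tx_length
    ts <- ts[which(keep)]
    fe <- fe[rownames(fe) %in% transcriptIds(ts), ]
  }
  usage <- computeUsage(fe, ts, tpm_floor = config$tpm_floor)
  usage <- empiricalPvalues(usage, fe)
  pairs <- callSwitches(usage, threshold = config$delta_tu_threshold,
                        alpha = config$alpha)
  out <- list(usage = usage, switch_pairs = pairs)
  tests <- list()
  if (nrow(pairs) >= 2) {
    lr <- classifyLengthRatio(pairs, ts)
    out$switch_pairs <- lr$pairs
    if (!is.null(lr$test)) tests$length_ratio_binomial <- lr$test
    if (sum(lr$pairs$category == "positive") >= 2)
      tests$exon_counts_positive <- compareExonCounts(lr$pairs, ts,
                                                      "positive")
  }
  events <- extractEvents(ts)
  psi <- computeDeltaPsi(events, fe, tpm_floor = config$tpm_floor)
  psi <- psiPvalues(psi, events, fe)
  out$events <- events
  out$psi <- psi
  out$psi_by_kind <- psiByKind(psi)
  ris <- selectNuclearRIs(psi, alpha = config$alpha)
  out$nuclear_ris <- ris$nuclear
  if (!is.null(config$fasta) && nrow(ris$all_ri) > 0) {
    genome <- readFASTA(config$fasta)
    ev_ri <- riIntrons(events)
    nuc_gr <- ev_ri[names(ev_ri) %in% ris$nuclear$event_id]
    all_gr <- ev_ri[names(ev_ri) %in% ris$all_ri$event_id]
    if (length(nuc_gr) >= 2 && length(all_gr) >= 2) {
      prof_n <- intronProfiles(nuc_gr, genome)
      prof_a <- intronProfiles(all_gr, genome)
      out$intron_profiles <- rbind(cbind(prof_n, set = "nuclear"),
                                   cbind(prof_a, set = "all_ri"))
      tests$ri_length <- compareFeature(prof_n, prof_a, "length")
      tests$ri_stem <- compareFeature(prof_n, prof_a,
                                      "mean_stem_probability")
      out$dinucleotide_ratios <- data.frame(
        dinucleotide = names(dinucleotideEnrichment(
          attr(prof_n, "sequences"), attr(prof_a, "sequences"))),
        ratio = unname(dinucleotideEnrichment(
          attr(prof_n, "sequences"), attr(prof_a, "sequences"))))
      if (!is.null(config$pwms))
        out$rbp_enrichment <- rbpEnrichment(readPWMs(config$pwms),
                                            attr(prof_n, "sequences"),
                                            attr(prof_a, "sequences"))
      if (!is.null(config$bed))
        out$repeat_enrichment <- repeatEnrichment(readBED(config$bed),
                                                  nuc_gr, all_gr)
    }
  }
  if (length(tests))
    out$tests <- do.call(rbind, c(tests, list(make.row.names = TRUE)))
  if (!is.null(config$out_dir))
    writeResults(out[!vapply(out, is.null, logical(1))], config$out_dir)
  invisible(out)
}
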