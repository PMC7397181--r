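#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with the study's
#' default conditions. Defaults: 200 two-isoform genes, an equal mix of the
#' seven event kinds, half the genes switching with |deltaTU| = 0.5, three
#' replicates per fraction with 10% lognormal TPM noise, nuclear retained
#' introns planted short (mean 150 nt), GC-boosted (+0.15), stem-bearing
#' (30 nt inverted repeat) and nucleus-biased by deltaPSI = -0.4.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer range (lo, hi), 2 or 3 isoforms.
#' @param event_mix named proportions over A3, A5, AF, AL, MX, RI, SE
#'   (must sum to 1).
#' @param frac_switching_genes proportion of genes with a planted usage
#'   switch.
#' @param switch_effect planted |deltaTU| of the switch pair.
#' @param n_replicates replicates per fraction.
#' @param noise_cv coefficient of variation of replicate TPM noise.
#' @param ri_nuclear_frac proportion of RI genes planted nucleus-biased.
#' @param ri_delta_psi planted inclusion shift: PSI_nuc - PSI_cyto of
#'   nuclear RI events.
#' @param ri_short_len,ri_bg_len mean intron length (nt) of nuclear RIs vs
#'   all other introns.
#' @param ri_gc_boost GC-fraction excess of nuclear RI interiors over the
#'   uniform background (0.5).
#' @param ri_stem_len arm length (nt) of the exact inverted repeat planted
#'   in nuclear RIs (0 disables).
#' @param planted_motifs character ids from the supplied PWM set whose
#'   consensus is inserted into every nuclear RI.
#' @param repeat_nuclear_rate,repeat_bg_rate probability of planting one
#'   SINE interval into a nuclear RI / background intron.
#' @param repeat_len planted repeat length (nt).
#' @param mono_nuclear plant the nuclear switch isoform as a mono-exonic
#'   (fully unspliced) transcript.
#' @param noncoding_nuclear mark nuclear switch isoforms as noncoding.
#' @param exon_len exon length range (nt).
#' @param max_exons most exons allowed per gene.
#' @param seed RNG seed (all generator stages derive their streams from
#'   it).
#' @return validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_genes = 200,
                             isoforms_per_gene = c(2, 2),
                             event_mix = NULL,
                             frac_switching_genes = 0.5,
                             switch_effect = 0.5,
                             n_replicates = 3,
                             noise_cv = 0.1,
                             ri_nuclear_frac = 0.5,
                             ri_delta_psi = 0.4,
                             ri_short_len = 150,
                             ri_bg_len = 1500,
                             ri_gc_boost = 0.15,
                             ri_stem_len = 30,
                             planted_motifs = character(0),
                             repeat_nuclear_rate = 0,
                             repeat_bg_rate = 0,
                             repeat_len = 80,
                             mono_nuclear = FALSE,
                             noncoding_nuclear = FALSE,
                             exon_len = c(80, 300),
                             max_exons = 8,
                             seed = 1L) {
  kinds <- c("A3", "A5", "AF", "AL", "MX", "RI", "SE")
  if (is.null(event_mix)) {
    event_mix <- rep(1 / 7, 7)
    names(event_mix) <- kinds
  }
  if (!setequal(names(event_mix), kinds))
    stop("event_mix must be named over ", paste(kinds, collapse = ", "))
  event_mix <- event_mix[kinds]
  if (abs(sum(event_mix) - 1) > 1e-9) stop("event_mix must sum to 1")
  props <- c(frac_switching_genes, ri_nuclear_frac, repeat_nuclear_rate,
             repeat_bg_rate, event_mix)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (switch_effect < 0 || switch_effect > 1 ||
      ri_delta_psi < 0 || ri_delta_psi > 1)
    stop("effect sizes must lie in [0, 1]")
  if (ri_short_len < 60 || ri_bg_len < 60)
    stop("intron mean lengths must be at least 60 nt")
  if (event_mix["MX"] > 0 && max_exons < 4)
    stop("MX events need at least 4 exons allowed")
  if (event_mix["SE"] > 0 && max_exons < 3)
    stop("SE events need at least 3 exons allowed")
  if (isoforms_per_gene[1] < 2 || isoforms_per_gene[2] > 3)
    stop("isoforms_per_gene must lie within 2..3")
  structure(list(
    n_genes = as.integer(n_genes), isoforms_per_gene = isoforms_per_gene,
    event_mix = event_mix, frac_switching_genes = frac_switching_genes,
    switch_effect = switch_effect, n_replicates = as.integer(n_replicates),
    noise_cv = noise_cv, ri_nuclear_frac = ri_nuclear_frac,
    ri_delta_psi = ri_delta_psi, ri_short_len = ri_short_len,
    ri_bg_len = ri_bg_len, ri_gc_boost = ri_gc_boost,
    ri_stem_len = as.integer(ri_stem_len), planted_motifs = planted_motifs,
    repeat_nuclear_rate = repeat_nuclear_rate,
    repeat_bg_rate = repeat_bg_rate, repeat_len = as.integer(repeat_len),
    mono_nuclear = mono_nuclear, noncoding_nuclear = noncoding_nuclear,
    exon_len = exon_len, max_exons = as.integer(max_exons),
    seed = as.integer(seed)), class = "SimulationConfig")
}

# sample one element from a vector (safe for length-1 vectors)
.sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

# shifted-geometric intron lengths: right-skewed like real introns
.intronLen <- function(n, mean_len, min_len = 70) {
  min_len + stats::rgeom(n, 1 / max(mean_len - min_len, 1))
}

#' Simulate a gene annotation with planted splicing events
#'
#' Each gene carries two (optionally three) isoforms differing by one local
#' event of a kind drawn from \code{event_mix}, built by explicit
#' exon-structure edits (RI: exon fusion across the intron; SE: internal
#' exon drop; A3/A5: acceptor/donor shift; AF/AL: alternative terminal
#' exon; MX: two mutually exclusive internal exons). Strand is random; on
#' minus-strand genes the mirrored genomic edit is applied so the planted
#' kind is the transcribed-strand kind. Each gene sits on its own
#' chromosome.
#'
#' @param config a \code{\link{simulationConfig}()}.
#' @return list with \code{ts} (a \linkS4class{TranscriptSet}) and
#'   \code{truth} (a \code{GroundTruth} list: \code{$genes} data.frame,
#'   \code{$motif_positions}, \code{$config}).
#' @export
simulateAnnotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  kinds <- names(config$event_mix)
  n <- config$n_genes
  kind_g <- sample(kinds, n, replace = TRUE, prob = config$event_mix)
  nuclear_ri <- kind_g == "RI" & stats::runif(n) < config$ri_nuclear_frac
  n_sw <- round(config$frac_switching_genes * n)
  cand <- which(!nuclear_ri)
  switching <- logical(n)
  if (n_sw > 0 && length(cand) > 0)
    switching[sample(cand, min(n_sw, length(cand)))] <- TRUE
  strand_g <- sample(c("+", "-"), n, replace = TRUE)
  iso_range <- config$isoforms_per_gene[1]:config$isoforms_per_gene[2]
  n_iso <- if (length(iso_range) == 1) rep(iso_range, n) else
    sample(iso_range, n, replace = TRUE)

  exl <- list(); gene_of <- character(0); biotype <- character(0)
  rows <- list()
  for (g in seq_len(n)) {
    gid <- sprintf("G%04d", g)
    chrom <- sprintf("chr%s", gid)
    res <- .makeGeneIsoforms(kind_g[g], strand_g[g], nuclear_ri[g],
                             n_iso[g], config)
    tx_ids <- sprintf("%s.t%d", gid, seq_along(res$isoforms))
    for (t in seq_along(res$isoforms)) {
      em <- res$isoforms[[t]]
      exl[[tx_ids[t]]] <- GRanges(chrom,
                                  IRanges(em[, 1], em[, 2]),
                                  strand = strand_g[g])
    }
    gene_of <- c(gene_of, rep(gid, length(tx_ids)))
    bt <- rep("coding", length(tx_ids))
    tc_id <- tn_id <- NA_character_
    if (switching[g]) {
      tc_id <- tx_ids[1]; tn_id <- tx_ids[2]
      if (config$mono_nuclear) {
        # replace the nuclear isoform with the fully unspliced transcript
        em1 <- res$isoforms[[1]]
        exl[[tx_ids[2]]] <- GRanges(chrom,
                                    IRanges(min(em1[, 1]), max(em1[, 2])),
                                    strand = strand_g[g])
      }
      if (config$noncoding_nuclear) bt[2] <- "noncoding"
    }
    biotype <- c(biotype, bt)
    rows[[g]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand_g[g], kind = kind_g[g],
      n_isoforms = length(tx_ids), is_switching = switching[g],
      tc_id = tc_id, tn_id = tn_id, is_nuclear_ri = nuclear_ri[g],
      inclusion_tx = res$inclusion_tx_index, exclusion_tx = 3L -
        res$inclusion_tx_index,
      event_start = res$event_intron[1], event_end = res$event_intron[2],
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  genes$inclusion_id <- sprintf("%s.t%d", genes$gene_id, genes$inclusion_tx)
  genes$exclusion_id <- sprintf("%s.t%d", genes$gene_id, genes$exclusion_tx)
  ts <- TranscriptSet(GRangesList(exl), gene_id = gene_of,
                      biotype = biotype)
  truth <- structure(list(genes = genes,
                          motif_positions = data.frame(),
                          config = config), class = "GroundTruth")
  list(ts = ts, truth = truth)
}

# Build the isoform exon matrices of one gene. Returns list(isoforms,
# inclusion_tx_index, event_intron = c(start, end) of the RI intron or the
# event anchor (NA, NA) otherwise).
.makeGeneIsoforms <- function(kind, strand, nuclear_ri, n_iso, config) {
  # on minus-strand genes apply the mirrored genomic edit
  eff <- if (strand == "+") kind else
    c(A3 = "A5", A5 = "A3", AF = "AL", AL = "AF", MX = "MX", RI = "RI",
      SE = "SE")[[kind]]
  n_ex <- switch(eff, RI = .sample1(2:4), SE = .sample1(3:5),
                 MX = .sample1(4:min(6, config$max_exons)),
                 .sample1(2:4))
  n_ex <- min(n_ex, config$max_exons)
  ex_len <- sample(config$exon_len[1]:config$exon_len[2], n_ex,
                   replace = TRUE)
  int_len <- .intronLen(max(n_ex - 1, 0), config$ri_bg_len)
  alt_len <- sample(config$exon_len[1]:config$exon_len[2], 1)
  event_intron <- c(NA_integer_, NA_integer_)
  inclusion_idx <- 1L

  if (eff == "RI") {
    k <- .sample1(seq_len(n_ex - 1))
    int_len[k] <- .intronLen(1, if (nuclear_ri) config$ri_short_len else
      config$ri_bg_len)
  } else if (eff == "AF") {
    int_len[1] <- alt_len + 200L
  } else if (eff == "AL") {
    int_len[n_ex - 1] <- alt_len + 200L
  } else if (eff == "MX") {
    k <- .sample1(seq_len(n_ex - 3))   # A = exon k+1, common flanks k, k+2
    int_len[k + 1] <- alt_len + 250L
  }
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- 101L
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    ends[i] <- pos + ex_len[i] - 1L
    pos <- ends[i] + (if (i < n_ex) int_len[i] else 0L) + 1L
  }
  chain <- cbind(start = starts, end = ends)
  iso2 <- chain
  if (eff == "SE") {
    k <- .sample1(2:(n_ex - 1))
    iso2 <- chain[-k, , drop = FALSE]
  } else if (eff == "RI") {
    event_intron <- c(ends[k] + 1L, starts[k + 1] - 1L)
    iso2 <- chain
    iso2[k, "end"] <- ends[k + 1]
    iso2 <- iso2[-(k + 1), , drop = FALSE]
    inclusion_idx <- 2L            # the fused isoform retains the intron
  } else if (eff == "A3") {
    # vary the genomic right end of an intron (acceptor on +)
    k <- .sample1(seq_len(n_ex - 1))
    delta <- .sample1(20:min(60, ex_len[k + 1] - 30))
    iso2[k + 1, "start"] <- starts[k + 1] + delta
    inclusion_idx <- 1L            # shorter intron = more included sequence
  } else if (eff == "A5") {
    k <- .sample1(seq_len(n_ex - 1))
    delta <- .sample1(20:min(60, ex_len[k] - 30))
    iso2[k, "end"] <- ends[k] - delta
    inclusion_idx <- 1L
  } else if (eff == "AF") {
    f2s <- ends[1] + 101L
    iso2[1, ] <- c(f2s, f2s + alt_len - 1L)
    inclusion_idx <- 1L            # distal (leftmost) first exon
  } else if (eff == "AL") {
    f2e <- starts[n_ex] - 101L
    iso2[n_ex, ] <- c(f2e - alt_len + 1L, f2e)
    inclusion_idx <- 1L
  } else if (eff == "MX") {
    bs <- ends[k + 1] + 101L
    iso2[k + 1, ] <- c(bs, bs + alt_len - 1L)
    # inclusion = 5'-most alternative exon in transcript orientation
    inclusion_idx <- if (strand == "+") 1L else 2L
  }
  isoforms <- list(chain, iso2)
  if (n_iso >= 3) {
    # bystander isoform: drop a different internal exon when possible
    iso3 <- chain
    if (n_ex >= 4) {
      drop_k <- if (eff == "SE") setdiff(2:(n_ex - 1), k) else 2:(n_ex - 1)
      if (length(drop_k)) iso3 <- chain[-drop_k[1], , drop = FALSE]
    }
    isoforms <- c(isoforms, list(iso3))
  }
  list(isoforms = isoforms, inclusion_tx_index = inclusion_idx,
       event_intron = event_intron)
}

# per-gene TU shares in each fraction (list of matrices iso x 2)
.plantedUsage <- function(truth) {
  cfg <- truth$config
  lapply(seq_len(nrow(truth$genes)), function(g) {
    row <- truth$genes[g, ]
    k <- row$n_isoforms
    spare <- if (k > 2) 0.2 * (k - 2) else 0
    S <- 1 - spare
    e <- cfg$switch_effect
    d <- cfg$ri_delta_psi
    if (isTRUE(row$is_switching)) {
      tu_c <- c(S / 2 + e / 2, S / 2 - e / 2)
      tu_n <- c(S / 2 - e / 2, S / 2 + e / 2)
    } else if (isTRUE(row$is_nuclear_ri)) {
      incl <- row$inclusion_tx
      tu_c <- tu_n <- numeric(2)
      tu_c[incl] <- S / 2 - d / 2; tu_c[3 - incl] <- S / 2 + d / 2
      tu_n[incl] <- S / 2 + d / 2; tu_n[3 - incl] <- S / 2 - d / 2
    } else {
      b <- stats::runif(1, 0.2, 0.8) * S
      tu_c <- tu_n <- c(b, S - b)
    }
    if (k > 2) {
      tu_c <- c(tu_c, rep(0.2, k - 2))
      tu_n <- c(tu_n, rep(0.2, k - 2))
    }
    cbind(cyto = tu_c, nuc = tu_n)
  })
}

#' Simulate fraction-specific expression with planted effects
#'
#' Gene expression is drawn log-uniform over [1, 1000] TPM. Switching genes
#' get usage shifted by +/- switch_effect/2 between fractions (so the
#' planted deltaTU equals switch_effect exactly in the noiseless limit);
#' nucleus-biased RI genes get the inclusion isoform's usage shifted by
#' ri_delta_psi toward the nucleus; all other genes have identical expected
#' usage in both fractions. Replicate TPMs carry multiplicative lognormal
#' noise with CV = noise_cv (mean exactly 1; zero CV gives exact values).
#'
#' @param ts TranscriptSet from [simulateAnnotation()].
#' @param truth matching GroundTruth.
#' @param config the \code{\link{simulationConfig}()}.
#' @return A \linkS4class{FractionExpression}.
#' @export
simulateExpression <- function(ts, truth, config) {
  set.seed(config$seed + 1L)
  genes <- truth$genes
  gene_tpm <- 10^stats::runif(nrow(genes), 0, 3)
  usage <- .plantedUsage(truth)
  nr <- config$n_replicates
  sdlog <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  samples <- c(sprintf("cyto_%d", seq_len(nr)),
               sprintf("nuc_%d", seq_len(nr)))
  fraction <- rep(c("cytoplasm", "nucleus"), each = nr)
  ids <- transcriptIds(ts)
  m <- matrix(0, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (g in seq_len(nrow(genes))) {
    tx <- sprintf("%s.t%d", genes$gene_id[g], seq_len(genes$n_isoforms[g]))
    mu <- cbind(matrix(gene_tpm[g] * usage[[g]][, "cyto"], ncol = nr,
                       nrow = length(tx)),
                matrix(gene_tpm[g] * usage[[g]][, "nuc"], ncol = nr,
                       nrow = length(tx)))
    noise <- if (sdlog > 0)
      matrix(exp(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog)),
             nrow = nrow(mu))
    else 1
    m[tx, ] <- mu * noise
  }
  FractionExpression(m, fraction, rep(seq_len(nr), 2))
}

#' Simulate an NMD-factor knockdown expression table
#'
#' Applies a per-transcript lognormal decay multiplier, drawn independently
#' of localization, to the control means, with fresh replicate noise: the
#' null condition in which NMD sensitivity does not differ between
#' cytoplasmic and nuclear transcripts.
#'
#' @param fe control \linkS4class{FractionExpression}.
#' @param config the \code{\link{simulationConfig}()}.
#' @param sdlog_decay lognormal sd of the decay multiplier, default log(2).
#' @return A \linkS4class{FractionExpression} with the same samples.
#' @export
simulateKnockdown <- function(fe, config, sdlog_decay = log(2)) {
  set.seed(config$seed + 2L)
  mult <- exp(stats::rnorm(nrow(fe), 0, sdlog_decay))
  sdlog <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  noise <- if (sdlog > 0)
    matrix(exp(stats::rnorm(length(tpm(fe)), -sdlog^2 / 2, sdlog)),
           nrow = nrow(fe))
  else 1
  FractionExpression(tpm(fe) * mult * noise, sampleFractions(fe),
                     colData(fe)$replicate)
}

.BASES <- c("A", "C", "G", "T")
.revcompChars <- function(x) rev(chartr("ACGT", "TGCA", x))

#' Simulate genome sequences with planted intron signals
#'
#' Chromosome sequences are uniform random DNA except that (i) every intron
#' of every isoform carries canonical GT..AG dinucleotides on the
#' transcribed strand, (ii) nuclear-RI intron interiors are GC-boosted by
#' ri_gc_boost, carry an exact inverted repeat (stem arms of ri_stem_len
#' separated by a >= 4 nt loop) and one consensus instance of each planted
#' motif, recorded in the returned truth's \code{motif_positions}
#' (transcribed-strand offsets).
#'
#' @param ts TranscriptSet from [simulateAnnotation()].
#' @param truth matching GroundTruth.
#' @param config the \code{\link{simulationConfig}()}.
#' @param pwms PWM list supplying the planted motif consensuses (needed
#'   when \code{planted_motifs} is non-empty).
#' @return list with \code{genome} (DNAStringSet) and updated
#'   \code{truth}.
#' @export
simulateSequences <- function(ts, truth, config, pwms = list()) {
  set.seed(config$seed + 3L)
  miss <- setdiff(config$planted_motifs, names(pwms))
  if (length(miss))
    stop("planted motifs without a PWM: ", paste(miss, collapse = ", "))
  exl <- txExons(ts)
  inl <- txIntrons(ts)
  genes <- truth$genes
  chroms <- list()
  motif_rows <- list()
  g_boost <- config$ri_gc_boost
  p_gc <- c((0.5 - g_boost) / 2, (0.5 + g_boost) / 2,
            (0.5 + g_boost) / 2, (0.5 - g_boost) / 2)
  tx_gene <- geneIds(ts)
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    txs <- names(tx_gene)[tx_gene == gid]
    ends <- max(vapply(txs, function(t) max(end(exl[[t]])), numeric(1)))
    len <- as.integer(ends + 100)
    seq_chars <- sample(.BASES, len, replace = TRUE)
    st <- genes$strand[g]
    # nuclear-RI intron interior: GC boost, stem, motifs
    if (isTRUE(genes$is_nuclear_ri[g]) && !is.na(genes$event_start[g])) {
      s <- genes$event_start[g]; e <- genes$event_end[g]
      L <- e - s + 1L
      interior <- (s + 2L):(e - 2L)
      seq_chars[interior] <- sample(.BASES, length(interior),
                                    replace = TRUE, prob = p_gc)
      toGenomic <- function(off) if (st == "+") s + off - 1L else e - off + 1L
      writeTx <- function(off, chars) {
        # write characters given in transcribed orientation at offset off
        if (st == "+") {
          seq_chars[(s + off - 1L):(s + off + length(chars) - 2L)] <<- chars
        } else {
          pos <- (e - off + 1L):(e - off - length(chars) + 2L)
          seq_chars[rev(pos)] <<- .revcompChars(chars)
        }
      }
      arm <- min(config$ri_stem_len, (L - 12L) %/% 2L)
      o1 <- NA_integer_; o2 <- NA_integer_
      if (arm >= 4) {
        loop <- 6L
        o1 <- max(3L, (L - (2L * arm + loop)) %/% 2L + 1L)
        o2 <- o1 + arm + loop
        left <- sample(.BASES, arm, replace = TRUE, prob = p_gc)
        writeTx(o1, left)
        writeTx(o2, .revcompChars(left))
      }
      for (mid in config$planted_motifs) {
        cons <- .pwmConsensusDNA(pwms[[mid]])
        kk <- length(cons)
        lo <- 3L; hi <- if (!is.na(o1)) o1 - kk - 1L else L - kk - 2L
        if (hi < lo) { lo <- if (!is.na(o2)) o2 + arm else 3L
                       hi <- L - kk - 2L }
        if (hi < lo) next
        off <- .sample1(lo:hi)
        writeTx(off, cons)
        motif_rows[[length(motif_rows) + 1L]] <-
          data.frame(gene_id = gid, motif_id = mid, offset = off,
                     stringsAsFactors = FALSE)
      }
    }
    # canonical boundaries on every intron of every isoform, written last
    for (t in txs) {
      im <- inl[[t]]
      for (i in seq_along(im)) {
        s <- start(im)[i]; e <- end(im)[i]
        if (st == "+") {
          seq_chars[s:(s + 1L)] <- c("G", "T")
          seq_chars[(e - 1L):e] <- c("A", "G")
        } else {
          seq_chars[s:(s + 1L)] <- c("C", "T")
          seq_chars[(e - 1L):e] <- c("A", "C")
        }
      }
    }
    chroms[[genes$chrom[g]]] <- paste(seq_chars, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  truth$motif_positions <- if (length(motif_rows))
    do.call(rbind, motif_rows) else data.frame()
  list(genome = genome, truth = truth)
}

.pwmConsensusDNA <- function(pwm) {
  chartr("U", "T", rownames(pwm)[apply(pwm, 2, which.max)])
}

#' Simulate a repeat annotation
#'
#' Plants one SINE interval inside the event intron of each RI gene with
#' probability \code{repeat_nuclear_rate} (nuclear RIs) or
#' \code{repeat_bg_rate} (background RIs and, at the background rate, all
#' other introns).
#'
#' @param ts TranscriptSet from [simulateAnnotation()].
#' @param truth matching GroundTruth.
#' @param config the \code{\link{simulationConfig}()}.
#' @return GRanges with \code{repeat_class}, possibly empty.
#' @export
simulateRepeats <- function(ts, truth, config) {
  set.seed(config$seed + 4L)
  genes <- truth$genes
  rows <- list()
  plant <- function(chrom, s, e, rate) {
    if (stats::runif(1) >= rate) return(NULL)
    L <- e - s + 1L
    w <- min(config$repeat_len, L - 20L)
    if (w < 10) return(NULL)
    off <- .sample1(0:(L - w - 10L)) + 5L
    GRanges(chrom, IRanges(s + off, s + off + w - 1L),
            repeat_class = "SINE")
  }
  inl <- txIntrons(ts)
  tx_gene <- geneIds(ts)
  for (g in seq_len(nrow(genes))) {
    if (!is.na(genes$event_start[g])) {
      rate <- if (isTRUE(genes$is_nuclear_ri[g]))
        config$repeat_nuclear_rate else config$repeat_bg_rate
      rows[[length(rows) + 1L]] <- plant(genes$chrom[g],
                                         genes$event_start[g],
                                         genes$event_end[g], rate)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(GRanges(seqnames = character(0), ranges = IRanges(),
                   repeat_class = character(0)))
  GRanges(vapply(rows, function(r) as.character(seqnames(r)), character(1)),
          IRanges(vapply(rows, start, integer(1)),
                  vapply(rows, end, integer(1))),
          repeat_class = vapply(rows, function(r) r$repeat_class,
                                character(1)))
}

#' A small set of sharp test PWMs
#'
#' Eight 6-mer motifs with 0.97 consensus-base probability per position,
#' usable both as planted signals and as unplanted controls.
#'
#' @return named list of PWMs (see [readPWMs()]).
#' @export
makeTestPWMs <- function() {
  # consensuses chosen pairwise dissimilar (fewer than 4 agreeing positions
  # at every alignment shift) so one motif's planted instances cannot fire
  # another motif's near-match threshold
  cons <- c(M1 = "GCAUGC", M2 = "CGGUGC", M3 = "GCCUUG", M4 = "UUCGUG",
            M5 = "CUCUGU", M6 = "UAGCUA", M7 = "GAAUAA", M8 = "CUAGAG")
  out <- lapply(names(cons), function(id) {
    bases <- strsplit(cons[[id]], "")[[1]]
    m <- matrix(0.01, 4, length(bases),
                dimnames = list(c("A", "C", "G", "U"), NULL))
    for (j in seq_along(bases)) m[bases[j], j] <- 0.97
    attr(m, "rbp_name") <- paste0("RBP_", id)
    m
  })
  names(out) <- names(cons)
  out
}

#' Write a complete synthetic fixture bundle
#'
#' Generates annotation, expression, genome, repeats and PWMs under one
#' config and writes GTF + FASTA + expression TSV (+ sample metadata) +
#' BED + PWM file + ground_truth.tsv to a directory. Identical config and
#' seed give a byte-identical bundle.
#'
#' @param config a \code{\link{simulationConfig}()}.
#' @param out_dir output directory.
#' @param pwms PWM list (defaults to [makeTestPWMs()]).
#' @return invisible list with the in-memory objects (\code{ts},
#'   \code{truth}, \code{fe}, \code{genome}, \code{repeats}, \code{paths}).
#' @export
bundleFixture <- function(config, out_dir, pwms = makeTestPWMs()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulateAnnotation(config)
  fe <- simulateExpression(ann$ts, ann$truth, config)
  sq <- simulateSequences(ann$ts, ann$truth, config, pwms)
  reps <- simulateRepeats(ann$ts, sq$truth, config)
  paths <- list(
    gtf = file.path(out_dir, "annotation.gtf"),
    fasta = file.path(out_dir, "genome.fa"),
    expression = file.path(out_dir, "expression.tsv"),
    bed = file.path(out_dir, "repeats.bed"),
    pwms = file.path(out_dir, "motifs.pwm"),
    truth = file.path(out_dir, "ground_truth.tsv"))
  writeGTF(ann$ts, paths$gtf)
  Biostrings::writeXStringSet(sq$genome, paths$fasta)
  writeExpression(fe, paths$expression)
  writeBED(reps, paths$bed)
  writePWMs(pwms, paths$pwms)
  utils::write.table(sq$truth$genes, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(ts = ann$ts, truth = sq$truth, fe = fe,
                 genome = sq$genome, repeats = reps, pwms = pwms,
                 paths = paths))
}
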