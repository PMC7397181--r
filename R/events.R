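#' Local alternative-splicing event extraction
#'
#' Classifies the seven local event types (A3, A5, AF, AL, MX, RI, SE) from
#' transcript exon structures by pairwise comparison of exon chains within
#' each gene, then defines each event's inclusion and exclusion transcript
#' sets gene-wide by coordinate tests, so PSI later uses all isoform
#' evidence. Strand resolves 3'/5' polarity: an intron's genomic left end is
#' the donor on the plus strand and the acceptor on the minus strand.
#'
#' @name splice-events
NULL

.hasIntron <- function(im, s, e) any(im[, 1] == s & im[, 2] == e)
.hasExon <- function(em, s, e) any(em[, 1] == s & em[, 2] == e)
.spansRange <- function(em, s, e) any(em[, 1] <= s & em[, 2] >= e)
.ikey <- function(m) paste(m[, 1], m[, 2], sep = "-")

# classify the structural differences between one transcript pair.
# em*/im*: exon and intron matrices (genomic coords); returns list(events,
# residual). Event descriptors: list(kind_raw, coords named int vector).
# kind_raw is strand-agnostic ("right_shift", "left_shift", "alt_left",
# "alt_right", "MX", "RI", "SE"); .resolveKind maps it by strand.
.classifyPair <- function(em1, im1, em2, im2) {
  k1 <- .ikey(im1); k2 <- .ikey(im2)
  d1 <- setdiff(k1, k2); d2 <- setdiff(k2, k1)
  used1 <- character(0); used2 <- character(0)
  events <- list()
  add <- function(kind_raw, coords) {
    events[[length(events) + 1L]] <<- list(kind_raw = kind_raw,
                                           coords = coords)
  }
  # --- MX: consecutive intron pairs flanking a single exon in each tx,
  # matching outer boundaries, disjoint middle exons
  if (nrow(im1) >= 2 && nrow(im2) >= 2) {
    for (i in seq_len(nrow(im1) - 1)) {
      ia <- im1[i, ]; ib <- im1[i + 1, ]
      if (!(k1[i] %in% d1) || !(k1[i + 1] %in% d1)) next
      a <- c(ia[2] + 1L, ib[1] - 1L)              # middle exon of tx1
      if (!.hasExon(em1, a[1], a[2])) next
      for (j in seq_len(nrow(im2) - 1)) {
        ja <- im2[j, ]; jb <- im2[j + 1, ]
        if (!(k2[j] %in% d2) || !(k2[j + 1] %in% d2)) next
        if (ja[1] != ia[1] || jb[2] != ib[2]) next
        b <- c(ja[2] + 1L, jb[1] - 1L)
        if (!.hasExon(em2, b[1], b[2])) next
        if (a[2] >= b[1] && b[2] >= a[1]) next     # must be disjoint
        left <- if (a[1] < b[1]) a else b
        right <- if (a[1] < b[1]) b else a
        add("MX", c(up_end = unname(ia[1]) - 1L,
                    a1 = unname(left[1]), b1 = unname(left[2]),
                    a2 = unname(right[1]), b2 = unname(right[2]),
                    down_start = unname(ib[2]) + 1L))
        used1 <- c(used1, k1[i], k1[i + 1]); used2 <- c(used2, k2[j], k2[j + 1])
      }
    }
  }
  # --- RI: intron of one tx fully inside an exon of the other, outer
  # exon boundaries matching
  riScan <- function(imA, kA, dA, emA, emB, side) {
    for (i in seq_len(nrow(imA))) {
      if (!(kA[i] %in% dA) || kA[i] %in% (if (side == 1) used1 else used2))
        next
      s <- imA[i, 1]; e <- imA[i, 2]
      sp <- which(emB[, 1] <= s - 1L & emB[, 2] >= e + 1L)
      if (length(sp) != 1) next
      up <- which(emA[, 2] == s - 1L); dn <- which(emA[, 1] == e + 1L)
      if (length(up) != 1 || length(dn) != 1) next
      if (emA[up, 1] != emB[sp, 1] || emA[dn, 2] != emB[sp, 2]) next
      add("RI", c(s = unname(s), e = unname(e)))
      if (side == 1) used1 <<- c(used1, kA[i]) else used2 <<- c(used2, kA[i])
    }
  }
  riScan(im1, k1, d1, em1, em2, 1L)
  riScan(im2, k2, d2, em2, em1, 2L)
  # --- SE: skip junction in one tx, two consecutive junctions flanking a
  # single exon in the other
  seScan <- function(imA, kA, dA, imB, kB, dB, emB, side) {
    for (i in seq_len(nrow(imA))) {
      if (!(kA[i] %in% dA) || kA[i] %in% (if (side == 1) used1 else used2))
        next
      s <- imA[i, 1]; e <- imA[i, 2]
      lft <- which(imB[, 1] == s & imB[, 2] < e)
      rgt <- which(imB[, 2] == e & imB[, 1] > s)
      if (length(lft) != 1 || length(rgt) != 1) next
      cs <- imB[lft, 2] + 1L; ce <- imB[rgt, 1] - 1L
      if (cs > ce || !.hasExon(emB, cs, ce)) next
      add("SE", c(s = unname(s), cs = unname(cs), ce = unname(ce),
                  e = unname(e)))
      if (side == 1) {
        used1 <<- c(used1, kA[i]); used2 <<- c(used2, kB[lft], kB[rgt])
      } else {
        used2 <<- c(used2, kA[i]); used1 <<- c(used1, kB[lft], kB[rgt])
      }
    }
  }
  seScan(im1, k1, d1, im2, k2, d2, em2, 1L)
  seScan(im2, k2, d2, im1, k1, d1, em1, 2L)
  # --- boundary shifts and alternative terminal exons
  rem1 <- which(k1 %in% setdiff(d1, used1))
  rem2 <- which(k2 %in% setdiff(d2, used2))
  for (i in rem1) {
    if (k1[i] %in% used1) next
    for (j in rem2) {
      if (k2[j] %in% used2 || k1[i] %in% used1) next
      a <- im1[i, ]; b <- im2[j, ]
      if (a[1] == b[1] && a[2] != b[2]) {
        # shared left end; compare downstream exons
        dn1 <- which(em1[, 1] == a[2] + 1L)
        dn2 <- which(em2[, 1] == b[2] + 1L)
        if (length(dn1) != 1 || length(dn2) != 1) next
        x1 <- em1[dn1, ]; x2 <- em2[dn2, ]
        if (x1[1] <= x2[2] && x2[1] <= x1[2]) {
          add("right_shift", c(s = unname(a[1]),
                               e_short = unname(min(a[2], b[2])),
                               e_long = unname(max(a[2], b[2]))))
          used1 <- c(used1, k1[i]); used2 <- c(used2, k2[j])
        } else if (dn1 == nrow(em1) && dn2 == nrow(em2) &&
                   i == nrow(im1) && j == nrow(im2)) {
          # alternative terminal exon on the genomic right
          fl <- rbind(x1, x2)[order(c(x1[1], x2[1]), decreasing = TRUE), ]
          ee <- c(a[2], b[2])[order(c(x1[1], x2[1]), decreasing = TRUE)]
          add("alt_right", c(c_end = unname(a[1]) - 1L,
                             f1s = unname(fl[1, 1]), f1e = unname(fl[1, 2]),
                             i1e = unname(ee[1]),
                             f2s = unname(fl[2, 1]), f2e = unname(fl[2, 2]),
                             i2e = unname(ee[2])))
          used1 <- c(used1, k1[i]); used2 <- c(used2, k2[j])
        }
      } else if (a[2] == b[2] && a[1] != b[1]) {
        up1 <- which(em1[, 2] == a[1] - 1L)
        up2 <- which(em2[, 2] == b[1] - 1L)
        if (length(up1) != 1 || length(up2) != 1) next
        x1 <- em1[up1, ]; x2 <- em2[up2, ]
        if (x1[1] <= x2[2] && x2[1] <= x1[2]) {
          add("left_shift", c(s_short = unname(max(a[1], b[1])),
                              s_long = unname(min(a[1], b[1])),
                              e = unname(a[2])))
          used1 <- c(used1, k1[i]); used2 <- c(used2, k2[j])
        } else if (up1 == 1 && up2 == 1 && i == 1 && j == 1) {
          fl <- rbind(x1, x2)[order(c(x1[1], x2[1])), ]
          ss <- c(a[1], b[1])[order(c(x1[1], x2[1]))]
          add("alt_left", c(f1s = unname(fl[1, 1]), f1e = unname(fl[1, 2]),
                            i1s = unname(ss[1]),
                            f2s = unname(fl[2, 1]), f2e = unname(fl[2, 2]),
                            i2s = unname(ss[2]),
                            c_start = unname(a[2]) + 1L))
          used1 <- c(used1, k1[i]); used2 <- c(used2, k2[j])
        }
      }
    }
  }
  residual <- length(setdiff(d1, used1)) + length(setdiff(d2, used2))
  list(events = events, residual = residual)
}

# map the strand-agnostic raw kind to the seven event labels
.resolveKind <- function(kind_raw, strand) {
  plus <- strand == "+"
  switch(kind_raw,
         RI = "RI", SE = "SE", MX = "MX",
         right_shift = if (plus) "A3" else "A5",
         left_shift = if (plus) "A5" else "A3",
         alt_left = if (plus) "AF" else "AL",
         alt_right = if (plus) "AL" else "AF",
         stop("unknown raw kind ", kind_raw))
}

# gene-wide inclusion/exclusion membership of one transcript for an event.
# Returns "incl", "excl" or NA. Inclusion conventions: RI = intron
# retained; SE = cassette exon included; A3/A5 = shorter intron (more
# exonic sequence); MX = 5'-most alternative exon in transcript
# orientation; AF/AL = the distal (outermost) terminal exon form.
.membership <- function(desc, em, im, strand) {
  co <- desc$coords
  plus <- strand == "+"
  test2 <- function(incl, excl) {
    if (incl && excl) "both" else if (incl) "incl" else if (excl) "excl"
    else NA_character_
  }
  switch(desc$kind_raw,
    RI = test2(.spansRange(em, co["s"] - 1L, co["e"] + 1L),
               .hasIntron(im, co["s"], co["e"])),
    SE = test2(.hasIntron(im, co["s"], co["cs"] - 1L) &&
                 .hasIntron(im, co["ce"] + 1L, co["e"]) &&
                 .hasExon(em, co["cs"], co["ce"]),
               .hasIntron(im, co["s"], co["e"])),
    right_shift = test2(.hasIntron(im, co["s"], co["e_short"]),
                        .hasIntron(im, co["s"], co["e_long"])),
    left_shift = test2(.hasIntron(im, co["s_short"], co["e"]),
                       .hasIntron(im, co["s_long"], co["e"])),
    MX = {
      formA <- .hasExon(em, co["a1"], co["b1"]) &&
        .hasIntron(im, co["up_end"] + 1L, co["a1"] - 1L) &&
        .hasIntron(im, co["b1"] + 1L, co["down_start"] - 1L)
      formB <- .hasExon(em, co["a2"], co["b2"]) &&
        .hasIntron(im, co["up_end"] + 1L, co["a2"] - 1L) &&
        .hasIntron(im, co["b2"] + 1L, co["down_start"] - 1L)
      if (plus) test2(formA, formB) else test2(formB, formA)
    },
    alt_left = {
      form1 <- nrow(em) > 0 && em[1, 1] == co["f1s"] &&
        em[1, 2] == co["f1e"] &&
        .hasIntron(im, co["i1s"], co["c_start"] - 1L)
      form2 <- nrow(em) > 0 && em[1, 1] == co["f2s"] &&
        em[1, 2] == co["f2e"] &&
        .hasIntron(im, co["i2s"], co["c_start"] - 1L)
      test2(form1, form2)   # form1 = distal (leftmost) by construction
    },
    alt_right = {
      n <- nrow(em)
      form1 <- n > 0 && em[n, 1] == co["f1s"] && em[n, 2] == co["f1e"] &&
        .hasIntron(im, co["c_end"] + 1L, co["i1e"])
      form2 <- n > 0 && em[n, 1] == co["f2s"] && em[n, 2] == co["f2e"] &&
        .hasIntron(im, co["c_end"] + 1L, co["i2e"])
      test2(form1, form2)   # form1 = distal (rightmost)
    })
}

#' Extract alternative-splicing events from annotation
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @return data.frame with columns event_id, gene_id, kind, chrom, strand,
#'   coords (dash-separated genomic anchors), and list-columns
#'   \code{inclusion} / \code{exclusion} of transcript ids. Attributes
#'   \code{"residual"} (unclassified pairwise intron differences) and
#'   \code{"discarded"} (events dropped because a transcript matched both
#'   forms or a side was empty).
#' @export
extractEvents <- function(ts) {
  emats <- .exonMatrices(ts)
  imats <- lapply(emats, .intronMatrix)
  gene <- unname(geneIds(ts))
  exl <- txExons(ts)
  chrom <- vapply(seq_along(exl), function(i)
    as.character(seqnames(exl[[i]]))[1], character(1))
  strand_tx <- vapply(seq_along(exl), function(i)
    as.character(strand(exl[[i]]))[1], character(1))
  names(chrom) <- names(strand_tx) <- transcriptIds(ts)
  residual <- 0L; discarded <- 0L
  rows <- list()
  for (g in unique(gene)) {
    txs <- transcriptIds(ts)[gene == g]
    if (length(txs) < 2) next
    found <- list()
    for (i in seq_len(length(txs) - 1)) {
      for (j in seq(i + 1, length(txs))) {
        res <- .classifyPair(emats[[txs[i]]], imats[[txs[i]]],
                             emats[[txs[j]]], imats[[txs[j]]])
        residual <- residual + res$residual
        for (ev in res$events) {
          key <- paste(ev$kind_raw, paste(ev$coords, collapse = "-"))
          if (is.null(found[[key]])) found[[key]] <- ev
        }
      }
    }
    st <- strand_tx[txs[1]]
    for (ev in found) {
      mem <- vapply(txs, function(tx)
        .membership(ev, emats[[tx]], imats[[tx]], st), character(1))
      if (any(!is.na(mem) & mem == "both")) { discarded <- discarded + 1L; next }
      incl <- txs[!is.na(mem) & mem == "incl"]
      excl <- txs[!is.na(mem) & mem == "excl"]
      if (length(incl) == 0 || length(excl) == 0) {
        discarded <- discarded + 1L; next
      }
      kind <- .resolveKind(ev$kind_raw, st)
      coords <- paste(ev$coords, collapse = "-")
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = paste(g, kind, coords, sep = ";"),
        gene_id = g, kind = kind, chrom = chrom[txs[1]], strand = st,
        coords = coords,
        inclusion = I(list(incl)), exclusion = I(list(excl)),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), gene_id = character(0),
               kind = character(0), chrom = character(0),
               strand = character(0), coords = character(0),
               inclusion = I(list()), exclusion = I(list()),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "residual") <- residual
  attr(out, "discarded") <- discarded
  out
}

#' Genomic intervals of retained-intron events
#'
#' @param events data.frame from [extractEvents()] (rows of kind RI).
#' @return GRanges of the retained introns, named by event id.
#' @export
riIntrons <- function(events) {
  ev <- events[events$kind == "RI", , drop = FALSE]
  if (nrow(ev) == 0)
    return(GRanges(seqnames = character(0), ranges = IRanges()))
  parts <- do.call(rbind, lapply(strsplit(ev$coords, "-", fixed = TRUE),
                                 as.integer))
  gr <- GRanges(ev$chrom, IRanges(parts[, 1], parts[, 2]),
                strand = ev$strand)
  names(gr) <- ev$event_id
  gr
}
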