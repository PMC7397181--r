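test_that("a skipped internal exon yields exactly one SE event", {
  for (st in c("+", "-")) {
    ev <- extractEvents(makeSEGene(st))
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$kind, "SE")
    expect_equal(ev$inclusion[[1]], "t1")
    expect_equal(ev$exclusion[[1]], "t2")
  }
})

test_that("an exon fused across an intron yields one RI event on that intron", {
  for (st in c("+", "-")) {
    ev <- extractEvents(makeRIGene(st))
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$kind, "RI")
    # the retained interval equals the spliced isoform's intron
    expect_equal(ev$coords, "201-300")
    expect_equal(ev$inclusion[[1]], "t2")  # fused isoform retains
    expect_equal(ev$exclusion[[1]], "t1")
    ri <- riIntrons(ev)
    expect_equal(start(ri), 201L)
    expect_equal(end(ri), 300L)
  }
})

test_that("acceptor and donor shifts resolve A3/A5 by strand", {
  mk <- function(shift_right, strand) {
    e1 <- GenomicRanges::GRanges("c1",
      IRanges::IRanges(c(101, 401), c(200, 500)), strand = strand)
    if (shift_right) {
      e2 <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(c(101, 431), c(200, 500)), strand = strand)
    } else {
      e2 <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(c(101, 401), c(170, 500)), strand = strand)
    }
    TranscriptSet(GenomicRanges::GRangesList(t1 = e1, t2 = e2),
                  gene_id = c("G1", "G1"))
  }
  # varying intron right end = acceptor on +, donor on -
  expect_equal(extractEvents(mk(TRUE, "+"))$kind, "A3")
  expect_equal(extractEvents(mk(TRUE, "-"))$kind, "A5")
  expect_equal(extractEvents(mk(FALSE, "+"))$kind, "A5")
  expect_equal(extractEvents(mk(FALSE, "-"))$kind, "A3")
  # inclusion is the shorter-intron (more exonic sequence) form
  ev <- extractEvents(mk(TRUE, "+"))
  expect_equal(ev$inclusion[[1]], "t1")
})

test_that("generator-planted kinds are recovered across all seven types", {
  cfg <- simulationConfig(n_genes = 140, seed = 41)
  ann <- simulateAnnotation(cfg)
  ev <- extractEvents(ann$ts)
  tg <- ann$truth$genes
  hit <- vapply(seq_len(nrow(tg)), function(g) {
    sub <- ev[ev$gene_id == tg$gene_id[g], , drop = FALSE]
    nrow(sub) == 1 && sub$kind == tg$kind[g]
  }, logical(1))
  expect_gte(mean(hit), 0.99)
  expect_equal(attr(ev, "residual"), 0L)
})

test_that("rule classifier agrees with the junction-set oracle", {
  cfg <- simulationConfig(n_genes = 120, seed = 42, max_exons = 6)
  ann <- simulateAnnotation(cfg)
  ev <- extractEvents(ann$ts)
  em <- SpliceLoc:::.exonMatrices(ann$ts)
  tg <- ann$truth$genes
  for (g in seq_len(nrow(tg))) {
    t1 <- sprintf("%s.t1", tg$gene_id[g])
    t2 <- sprintf("%s.t2", tg$gene_id[g])
    ok <- oracleEventKind(em[[t1]], em[[t2]], tg$strand[g])
    sub <- ev[ev$gene_id == tg$gene_id[g], , drop = FALSE]
    expect_equal(sub$kind, ok, info = tg$gene_id[g])
  }
})

test_that("PSI follows the inclusion-ratio definition", {
  ts <- makeRIGene()
  ev <- extractEvents(ts)
  # inclusion (t2) 30 TPM, exclusion (t1) 10 TPM -> PSI 0.75
  fe <- makeExpression(ts, c(t1 = 10, t2 = 30), c(t1 = 30, t2 = 10))
  psi <- computeDeltaPsi(ev, fe)
  expect_equal(psi$psi_cyto, 0.75)
  expect_equal(psi$psi_nuc, 0.25)
  expect_equal(psi$delta_psi, 0.5)
  # equal inclusion and exclusion -> PSI 0.5 in both fractions, dPSI 0
  fe2 <- makeExpression(ts, c(t1 = 20, t2 = 20), c(t1 = 5, t2 = 5))
  psi2 <- computeDeltaPsi(ev, fe2)
  expect_equal(psi2$psi_cyto, 0.5)
  expect_equal(psi2$delta_psi, 0)
  # below-floor events are skipped and counted
  fe3 <- makeExpression(ts, c(t1 = 0.2, t2 = 0.2), c(t1 = 9, t2 = 9))
  psi3 <- computeDeltaPsi(ev, fe3)
  expect_equal(nrow(psi3), 0L)
  expect_equal(attr(psi3, "skipped"), 1L)
})

test_that("PSI bounds and swap properties hold on random tables", {
  for (seed in 1:5) {
    d <- randomUsageTable(seed)
    ev <- extractEvents(d$ts)
    psi <- computeDeltaPsi(ev, d$fe)
    expect_true(all(psi$psi_cyto >= 0 & psi$psi_cyto <= 1))
    expect_true(all(psi$psi_nuc >= 0 & psi$psi_nuc <= 1))
    expect_true(all(abs(psi$delta_psi) <= 1))
    # complementarity: swapping inclusion/exclusion maps PSI -> 1 - PSI
    ev2 <- ev
    tmp <- ev2$inclusion; ev2$inclusion <- ev2$exclusion
    ev2$exclusion <- tmp
    psi2 <- computeDeltaPsi(ev2, d$fe)
    expect_equal(psi2$psi_cyto, 1 - psi$psi_cyto)
    expect_equal(psi2$delta_psi, -psi$delta_psi)
    # fraction-swap antisymmetry
    psi3 <- computeDeltaPsi(ev, swapFractions(d$fe))
    expect_equal(psi3$delta_psi, -psi$delta_psi)
  }
})

test_that("nuclear RI selection applies both cutoffs", {
  psi <- data.frame(event_id = c("e1", "e2", "e3", "e4"),
                    gene_id = "G", kind = c("RI", "RI", "RI", "SE"),
                    psi_cyto = 0.3, psi_nuc = 0.7,
                    delta_psi = c(-0.4, -0.4, 0.4, -0.4),
                    p_value = c(0.01, 0.2, 0.01, 0.01))
  sel <- selectNuclearRIs(psi)
  expect_equal(sel$nuclear$event_id, "e1")
  expect_equal(sort(sel$all_ri$event_id), c("e1", "e2", "e3"))
})

test_that("per-kind summaries report medians and flag low power", {
  psi <- data.frame(event_id = sprintf("e%d", 1:12), gene_id = "G",
                    kind = rep(c("RI", "SE"), each = 6),
                    psi_cyto = 0.5, psi_nuc = 0.5,
                    delta_psi = c(rnorm(6, -0.4, 0.01), rnorm(6, 0, 0.01)),
                    p_value = NA_real_)
  bk <- psiByKind(psi)
  expect_equal(bk$kind, c("RI", "SE"))
  expect_lt(bk$median_delta_psi[1], -0.3)
  expect_false(any(bk$low_power))
  one <- psiByKind(psi[psi$kind == "RI", ])
  expect_equal(nrow(one), 1L)
})
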