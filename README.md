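# SpliceLoc

Alternative splicing does not only change what a transcript encodes — it
changes where the transcript lives. When cytoplasmic and nuclear fractions
of the same cells are RNA-sequenced separately, isoforms of one gene often
split between compartments, and intron retention in particular accompanies
nuclear residence. SpliceLoc is an R package for analysts working with such
subcellular-fraction RNA-seq: starting from transcript-level TPM tables, it
identifies isoform switches between cytoplasm and nucleus, attributes them
to local splicing decisions, and characterizes the retained introns that
travel with nuclear transcripts.

## What it computes

**Transcript usage switches.** For transcript *T* of gene *G*, usage is
*TU = T/G* per fraction (gene TPM = sum of its transcripts), and

> ΔTU = T_c/G_c − T_n/G_n

so positive ΔTU marks cytoplasm-enriched isoforms. Significance is
empirical: the null is built from between-replicate usage differences,
pooled across transcripts of similar expression and rescaled to the
sampling scale of the replicate-mean statistic. A switch pair is a gene
with a significant cytoplasmic transcript (ΔTU > 0.2, p < 0.05) and a
significant nuclear one (ΔTU < −0.2, p < 0.05).

**Splicing events and inclusion.** The seven local event kinds (SE, RI,
A3, A5, AF, AL, MX) are classified from the GTF by pairwise exon-chain
comparison, with gene-wide inclusion/exclusion transcript sets. Inclusion
is Ψ = ΣTPM_incl / (ΣTPM_incl + ΣTPM_excl) per fraction; ΔΨ = Ψ_cyto −
Ψ_nuc, so negative ΔΨ means nuclear preference. Nuclear RIs are RI events
with ΔΨ < 0 and p < 0.05.

**Intron characterization.** Length and splice-boundary composition;
base-pairing ("stem") probabilities from an exact McCaskill-style
partition function over nested structures with a uniform per-pair energy
(oracle-tested against exhaustive enumeration); dinucleotide enrichment;
PWM-based RBP-motif densities with exact score-quantile thresholds and
permutation significance; repeat-class overlap enrichment.

**Synthetic data with ground truth.** A first-class generator plants
switches, all seven event kinds, nucleus-biased retained introns (short,
GC-rich, stem-bearing, motif-carrying), repeats and NMD-knockdown tables,
and records everything it planted — the basis of the package's
parameter-recovery tests.

## Worked example

```r
library(SpliceLoc)

cfg <- simulationConfig(n_genes = 60, seed = 3)
ann <- simulateAnnotation(cfg)
fe  <- simulateExpression(ann$ts, ann$truth, cfg)

usage <- empiricalPvalues(computeUsage(fe, ann$ts), fe)
pairs <- callSwitches(usage)
nrow(pairs)
#> [1] 35

events <- extractEvents(ann$ts)
psi <- psiPvalues(computeDeltaPsi(events, fe), events, fe)
psiByKind(psi)[, c("kind", "n", "median_delta_psi")]
#>   kind  n median_delta_psi
#> 1   A3  7      0.484643581
#> 2   A5  8      0.249039737
#> 3   AF 14      0.460579512
#> 4   AL  8      0.492593414
#> 5   MX  8     -0.001426055
#> 6   RI  7     -0.418941894
#> 7   SE  7      0.042522681

nrow(selectNuclearRIs(psi)$nuclear)
#> [1] 7
```

Thirty-five genes switch isoforms between fractions (half the genes carry
a planted switch of |ΔTU| = 0.5; the RI genes' planted nuclear bias also
exceeds the switch thresholds). The per-kind ΔΨ medians show the planted
pattern: retained introns sit at median ΔΨ ≈ −0.42 (nuclear), while kinds
hit only by usage switches inherit those shifts and MX/SE stay near zero.
Seven RI events pass the nuclear-RI selection.

With a genome, the intron-level comparison runs the same way:

```r
sq <- simulateSequences(ann$ts, ann$truth, cfg)
ri <- riIntrons(events)
prof <- intronProfiles(ri, sq$genome)
compareFeature(prof[1:3, ], prof, "mean_stem_probability")
```

A config-driven driver, `runLocalizationAnalysis()`, reads a YAML file
naming the GTF/TPM/FASTA/BED/PWM inputs and writes all result tables as
TSV (`usage`, `switch_pairs`, `events`, `psi`, `nuclear_ris`,
`intron_profiles`, enrichments).

## Scope

SpliceLoc starts from TPM tables: read mapping and abundance estimation
are out of scope, as are GO databases (gene-set enrichment accepts
user-supplied sets), thermodynamically parameterized folding, and
proprietary motif databases (PWMs are inputs). The methods vignette
(`vignettes/splicing-localization-methods.Rmd`) documents the models,
parameter choices, fixture design and known limitations.
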