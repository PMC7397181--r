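---
title: "Methods: localization-associated alternative splicing from fractionated RNA-seq"
author: "SpliceLoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localization-associated alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When a cell lysate is split into cytoplasmic and nuclear fractions and both
are sequenced, isoforms of the same gene often distribute unequally between
the two compartments. SpliceLoc quantifies that imbalance from
transcript-level TPM tables, asks which local splicing decisions drive it,
and characterizes the retained introns that accompany nuclear residence.
The pipeline operates entirely downstream of quantification: its inputs
are a GTF annotation, a transcript x sample TPM matrix with
fraction/replicate labels, and optionally a genome FASTA, a repeat BED and
a set of RBP position weight matrices.

# Transcript usage and switches

For transcript $T$ of gene $G$, usage in a fraction is $TU = T/G$, with the
gene TPM $G$ taken as the sum of its transcripts' TPM, so usage sums to one
per gene and fraction by construction. The localization statistic is

$$\Delta TU = T_c/G_c - T_n/G_n$$

(cytoplasm minus nucleus): positive values mark cytoplasm-enriched
isoforms. Point estimates use replicate-mean TPM. A *switch pair* for a
gene is a cytoplasmic transcript Tc maximizing $\Delta TU$ among
transcripts with $\Delta TU > 0.2$ and $p < 0.05$, and a nuclear
transcript Tn minimizing it among those with $\Delta TU < -0.2$ and
$p < 0.05$; both must exist. The 0.2 threshold and 0.05 level are
configurable (`callSwitches()`); 0.2 is the default because it is the
value used in the switch definition itself, while 0.25 appears in some
genome-wide filtering contexts — the parameter exists precisely because
reasonable analyses differ here.

## Empirical significance

Replicates carry the only information about technical variability, so
significance is empirical rather than parametric. For each fraction, every
pair of replicates yields per-transcript usage differences; these are
pooled across transcripts of similar expression (five quantile bins of
log10 gene TPM — low-expression transcripts have noisier usage, so nulls
must be matched on expression) and form the null distribution, with
$p = (1 + \#\{|null| \ge |obs|\})/(1 + N)$.

One calibration detail matters: a difference between two single replicates
has variance $2\sigma^2$, while the observed statistic is a difference of
replicate *means* with variance $\sigma^2(1/n_c + 1/n_n)$. The null values
are therefore rescaled by $\sqrt{(1/n_c + 1/n_n)/2}$. Without this the
null is too wide, p-values pile up near 1, and nominal levels are not
attained; with it, null simulations give uniform p-values (the test suite
checks this with a Kolmogorov–Smirnov test at 500 null genes) and the
false-positive rate at 0.05 stays near 0.05. The same machinery is reused
for event inclusion levels.

# Local splicing events and inclusion

Seven local event kinds are classified from the annotation by pairwise
comparison of exon chains within each gene: skipped exon (SE), retained
intron (RI), alternative 3'/5' splice sites (A3/A5), alternative
first/last exons (AF/AL) and mutually exclusive exons (MX). Detection
works on genomic coordinates with strand-agnostic patterns (e.g. "the
intron's right boundary moved") that are mapped to event labels by strand,
so minus-strand genes are handled by symmetry rather than by a second rule
set. Inclusion and exclusion transcript sets are then assigned *gene-wide*
by coordinate tests, so an event supported by two isoforms still counts
every other compatible isoform when inclusion is quantified. Transcripts
consistent with both forms would make the sets overlap; such events are
discarded and counted, which is the conservative option. Unclassifiable
pairwise differences are tallied in a `residual` attribute, never silently
dropped.

Inclusion of an event is $\Psi = \sum TPM_{incl} / (\sum TPM_{incl} + \sum
TPM_{excl})$ per fraction on replicate-mean TPM, and $\Delta\Psi =
\Psi_{cyto} - \Psi_{nuc}$, so *negative* $\Delta\Psi$ means the inclusion
form prefers the nucleus. Events below 1 TPM total in either fraction are
skipped (and counted): inclusion ratios of barely expressed events are
noise. Nuclear RIs are RI events with $\Delta\Psi < 0$ and $p < 0.05$; the
comparison background for their sequence features is the full set of
quantified RI events, which matches how "all retained introns" is used as
a control in this kind of analysis (all annotated introns can be
substituted by passing a different GRanges).

Inclusion-set conventions where the definitions leave freedom: RI
inclusion = the intron-retaining form; SE = cassette included; A3/A5 = the
shorter intron (more exonic sequence); MX = the 5'-most alternative exon
in transcript orientation; AF/AL = the distal terminal exon. These choices
only fix the sign of $\Psi$ per event; both orientations are equivalent
under the complementarity invariant ($\Psi \to 1-\Psi$), which the tests
assert.

# Stem probabilities

RNA structural stability is summarized as the mean probability that a base
is paired under a Boltzmann ensemble of nested secondary structures. The
model is deliberately minimal: Watson–Crick plus GU wobble pairs, minimum
hairpin loop of 3 nt, and one uniform energy per pair with Boltzmann
weight $e^2$ (about $2RT$ per stacked pair). The analysis uses the mean
stem probability only as a *relative* statistic between intron sets, for
which any monotone-consistent pairing model suffices; full
thermodynamic parameters, dangles and pseudoknots are out of scope. The
weight $e^2$ was fixed so that designed helices (an exact inverted repeat)
clearly dominate the ensemble against a random-sequence background while
keeping the background pairedness away from saturation.

Computationally, an unambiguous grammar over nested structures gives an
$O(n^3)$ inside/outside algorithm for exact pair probabilities; values are
rescaled by a per-base factor chosen adaptively near the ensemble growth
rate, because the unscaled partition function overflows doubles beyond a
few hundred nucleotides. The mean pairedness used in set comparisons is
computed faster as $2\,\mathbb{E}[\text{pairs}]/n$ via the derivative of
$\log Z$ in a single inside pass. Both routes are tested against exhaustive
enumeration of all structures for sequences up to 12 nt (tolerance 1e-9)
and against each other. Sequences beyond a configurable cap (default
2000 nt) are scored on a centered window and flagged.

# Motifs and repeats

PWM scanning is a plain log2-odds scan against a uniform background on the
sense (transcribed) strand only, since RBPs bind RNA. The hit threshold is
the exact upper quantile of the PWM's score distribution over all k-mers,
computed by dynamic programming over positions (and checked against full
$4^k$ enumeration in the tests); "score at least t where
$P(S \ge t) \le 1 - q$" avoids the degenerate thresholds that sharp PWMs
produce under the CDF reading. Enrichment between intron sets compares hit
densities per kilobase, with significance from permutations of the intron
set labels (sizes preserved) and BH correction across motifs. Repeat-class
enrichment works identically on overlapped-base fractions computed by
exact interval intersection. Proprietary scoring schemes (weighted ranks,
conservation filters) are intentionally not reproduced; the permutation
approach is self-contained and testable.

# The synthetic-data generator

Every downstream claim is validated on data with a planted ground truth.
The generator builds genes on their own chromosomes, each with two (or
three) isoforms differing by exactly one event constructed by explicit
exon-structure edits; strand is random and minus-strand genes receive the
mirrored genomic edit so the planted label is the transcribed-strand kind.
Defaults encode the study conditions used throughout the tests: 200
two-isoform genes, an equal event mix, half the genes switching with
$|\Delta TU| = 0.5$, three replicates per fraction, 10% replicate noise,
and nuclear RIs planted short (mean 150 nt vs 1500 nt background,
shifted-geometric lengths, right-skewed like real introns), GC-boosted by
0.15, carrying a 30 nt exact inverted repeat and $\Delta\Psi = -0.4$
toward the nucleus.

Expression noise is multiplicative lognormal with mean exactly one and CV
as configured, so the noiseless limit reproduces planted values exactly —
the basis of the exactness tests. Gene expression is log-uniform on
[1, 1000] TPM so low-expression edge cases arise naturally. Switching
roles and nuclear-RI roles are assigned to disjoint gene sets; otherwise a
single two-isoform gene would have to carry two conflicting usage shifts.
All splice boundaries carry canonical GT..AG dinucleotides on the
transcribed strand, which is also what makes the boundary-matrix "no
splice-signal difference" check meaningful.

Two fixture-design points deserve emphasis. First, the repeat-enrichment
check plants SINE intervals at a 5x per-intron rate difference and uses
*equal* length distributions in the two intron sets, because the
overlapped-base-fraction ratio equals the rate ratio only when lengths
match; with the default short-vs-long lengths the ratio would conflate
rate and length. Second, the motif-recovery fixture disables the GC boost
and plants only the motif: GC-biased composition shifts the chance-hit
rates of GC-rich and AT-rich PWMs in opposite directions, which is a real
confound worth testing separately but would make "only the planted motif
is significant" unattainable by construction. The same fixture scans at a
near-exact-match stringency (score quantile 0.999) because its premise is
a motif present in every nuclear RI and nowhere else — at looser
stringencies chance hits dominate both sets and the planted instances are
a small perturbation on top. The bundled test PWMs use pairwise
dissimilar consensuses (fewer than four agreeing positions at any
alignment shift) so that one motif's planted instances cannot fire
another motif's near-match threshold.

What the generator does not emulate: read-level sampling (quantification
noise enters only as the lognormal CV), ORF/codon structure, NMD features
beyond a per-transcript decay multiplier, overlapping genes, and
annotation errors. Passing tests therefore demonstrate correctness of the
statistical machinery under its stated model, not robustness to
quantification artifacts in real data.

# NMD sensitivity and the remaining comparisons

NMD sensitivity is the pseudo-counted log2 fold-change of expression after
knockdown of an NMD factor (c = 0.01 TPM guards ratios of barely expressed
transcripts); posterior fold-change machinery is unnecessary for this
definition. The switch-level comparisons use Mood's median test (ties at
the grand median go to the "at or below" cell; chi-square with continuity
correction when all expected counts reach 5, Fisher's exact otherwise),
Welch's two-tailed t-test (intron lengths on log10 scale — they are
heavy-tailed), the exact two-sided binomial test, and hypergeometric
gene-set enrichment with BH FDR. All are validated against closed forms or
enumeration oracles in the test suite.

# Problem sizes

The test and acceptance fixtures use 40–1000 genes depending on what the
check needs: 1000 planted events for classifier accuracy, 500 null genes
for calibration, 200 genes for switch recovery, 56 RI genes for the
sequence-feature comparisons (folding a 1500 nt intron costs about two
seconds at the default cap), 10–20 generator seeds for the
recovery-rate checks. These sizes were chosen to make sampling error small
relative to the tested margins.

# Known limitations

- The empirical null pools across transcripts within expression bins;
  transcripts of the same two-isoform gene contribute mirrored values, so
  p-values within a gene are not independent (the calibration check uses
  one transcript per gene).
- Event classification assumes isoforms share TSS/TES except where an
  AF/AL event is planted; annotation dialects with ragged terminal exons
  would enlarge the residual table rather than produce wrong labels.
- The structure model's absolute probabilities are not thermodynamic;
  only comparisons between sequence sets are meaningful.
- With three or more isoforms the planted usage shift is exact for the
  event pair only; bystander isoforms dilute $\Psi$ when they are
  compatible with one of the forms.
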