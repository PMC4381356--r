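---
title: "Bin-based differential splicing: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based differential splicing: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binsplice)
```

## The problem

Multi-isoform gene annotations make "the expression of an exon" ambiguous:
a genomic interval can be exonic in one isoform and intronic in another.
`binsplice` resolves this by flattening each gene into *bins* — maximal
subgenic intervals within which every transcript of the gene has uniform
exon/intron status.  Cutting the gene span at every annotated exon
boundary guarantees this uniformity.  Each bin is then classified:

* **exon-bin** — exonic in every transcript spanning it;
* **intron-bin** — intronic in every spanning transcript (a constitutive
  intron piece; the substrate for detecting *novel* intron retention);
* **AS-bin** — mixed status, i.e. a region directly involved in an
  annotated alternative-splicing event.

AS-bins carry an event class derived from the flanking-base topology in
the transcripts where the bin is intronic: flanks `(intron, intron)`
mean a skipped exon (ES), `(exon, exon)` a retained intron (IR), and one
exonic flank an alternative 5' or 3' splice site, with the 5'/3'
assignment following the transcription direction (strand).  When
different intronic transcripts disagree, or a flank falls outside a
transcript's span, the bin is classified `multiple`.  This makes the
per-bin decision rule total: every AS-bin receives exactly one class.
Bins covered by no transcript span at all (possible when two isoforms'
spans are disjoint within one gene) are treated as intronic.

Unlike exon-centric differential-usage partitions, introns are kept as
first-class bins.  That is the point of the design: changes in
constitutive introns (novel intron retention) are invisible to methods
that only quantify annotated exonic parts.

## Counting

A read supports a bin when any of its aligned (CIGAR `M`) segments
overlaps the bin by at least one nucleotide.  `N` gaps are *not*
overlap: a junction read that jumps an intron contributes nothing to the
intron bin it spans — this is what lets intron bins measure retention
rather than flanking-exon expression.  A gene's count is the number of
distinct reads hitting at least one of its bins, so a junction read
counts once for the gene however many exon bins it touches.  Counting is
unstranded by default (typical poly-A library protocols are unstranded);
a `stranded` option exists.  Bins overlapping a different gene on either
strand are flagged *ambiguous* and excluded from counting, avoiding
double attribution; the cost is a small loss of signal in overlapping
loci.  Multimapped reads are counted where their primary alignment lies;
secondary and duplicate-flagged alignments are skipped.

Read *density* is count divided by feature length (reads/nt).  The gene
density denominator is the gene's exonic length — the union of its exon-
and AS-bins — not the genomic span: gene expression is carried by
exonic sequence, and using the span would deflate densities of
intron-rich genes.

## The statistical core

Counts across replicates are modelled as negative binomial with a
**common dispersion** $\phi$ ($\mathrm{Var} = \mu + \phi\mu^2$),
estimated once per analysis level (genes; bins) by maximizing the
conditional log-likelihood given per-group totals — the classic
conditional-ML estimator for equal-library NB counts — over a log-spaced
grid refined by golden-section search.  Poisson data drive the estimate
to the $\phi = 0$ boundary, which is returned as exactly zero.

The two-group test is a **conditional exact test**: after equalizing
library sizes, replicate counts are summed per group; under a common
$\phi$ the group sum of $n$ replicates is NB with size $n/\phi$, and the
split of the total between the two groups follows a negative
hypergeometric distribution free of the unknown mean ($\phi = 0$ reduces
exactly to a binomial).  The two-sided p-value sums the probabilities of
every split no more likely than the observed one, capped at 1 — a
"double tail" rule that remains well defined for asymmetric conditional
distributions.  The test suite verifies this p-value against brute-force
enumeration via products of NB densities for all totals up to 30, and
against an independent reference implementation at equal library sizes
(agreement to $10^{-14}$).

Two numerical choices matter here:

* **Library equalization.**  For the conditional enumeration, counts are
  mapped through mid-quantiles to the geometric-mean library size
  (`quantile_equalize()`), which preserves the NB distribution shape.
  Plain proportional scaling changes the variance-to-mean relationship
  of a count and proved measurably anticonservative with unequal
  libraries.  The log2 fold change, by contrast, uses proportionally
  scaled (CPM-style) group means, which makes it exactly invariant to
  rescaling counts and libraries by a common factor; a 0.5 pseudo-count
  enters both groups only when either mean is zero.
* **Normalization.**  The effective library size is the total of
  assigned reads.  This is deliberate and simple, but carries the known
  composition bias when many genes change in one direction: the changed
  genes inflate one condition's totals and shift every null gene.  A
  trimmed-mean-of-M-values option (`normalization = "tmm"`, own compact
  implementation) is available for such designs and is demonstrated in
  the test suite to restore calibrated calls under a 10% one-sided
  differential-expression burden.

FDR control is Benjamini–Hochberg throughout.

## Differential expression

Genes with a mean raw count below 10 in *any* condition are discarded
before testing — the strict all-conditions reading keeps low-information
genes out of the dispersion fit.  A gene is called up- or down-regulated
when FDR < 0.10 **and** |log2 FC| > 0.58 (about 1.5-fold), both strict
inequalities.  Cross-genotype bookkeeping (`overlap_sets()`) counts
concordant and antagonistic calls between two contrasts.

## Differential splicing

For each bin, the **Splicing Index** (SI) in a genotype is bin density
divided by gene density — a length-normalized inclusion measure — and
the **Splicing Index Ratio** (SIR) is the mutant SI over the wild-type
SI, computed from per-genotype mean densities (not per-replicate SIs
averaged: the SI is defined as a property of a genotype's pooled
expression state).  The filter cascade, in order:

1. drop ambiguous bins;
2. drop bins of monoexonic genes (no splicing to measure);
3. drop bins with mean raw count below 5 in any condition;
4. drop bins of genes with read density at or below 0.05 in any genotype;
5. drop bins whose SI is at or below 0.05 in every *contrast* genotype.

Filters 3–4 run over all genotypes of the design (the same
all-conditions logic as the expression filter); filter 5 runs over the
contrast genotypes so the BH family contains only bins analyzable in
that contrast.  Retained AS-bins and intron-bins are tested with the
exact test on raw bin counts; the log2 fold change is taken on bin
densities, and BH adjustment runs *separately* within the AS-bin family
and the intron-bin family, because the two are reported as separate
analyses with separate tallies.  A bin is **altered** when all three
strict thresholds hold: |log2 FC| > 0.58, FDR < 0.15, |log2 SIR| > 0.58.
The SIR guard is the scientifically important one: a gene whose
expression changes uniformly moves bin density and gene density
together, leaves the SIR at zero, and is never called altered however
large its fold change — a property the test suite checks on constructed
fixtures.

## Enrichment and splice-site composition

Gene-list enrichment uses the **representation factor**
$\mathrm{RF} = kN/(n_1 n_2)$ — observed overlap over the overlap
expected for independent draws from a universe of size $N$ — with
hypergeometric tail probabilities in the direction indicated by the RF.
No multiple-testing correction is applied across categories by default
(raw $p \le 0.05$ is flagged), with a BH option.  The default universe
is the set of genes surviving the expression filter; a whole-genome
universe is a matter of passing a different `universe` vector.

For the most affected intron-retention events (at least 2-fold SIR
change at FDR ≤ 0.1 — inclusive bounds, unlike the strict altered-bin
call), donor and acceptor windows are extracted around the splice sites:
donor windows cover 3 exonic and 10 intronic bases by default (positions
−3..−1, +1..+10 reading 5'→3'), acceptors mirror this at the intron 3'
end; minus-strand windows are reverse-complemented so all sequences read
in the transcription direction.  Per-position nucleotide frequencies are
compared with a background of all annotated GT..AG introns (the terminal
dinucleotide rule approximates the major-spliceosome intron set; minor
U12-type GT-AG introns are rare and not separately distinguished).  Each
matrix cell gets an RF (foreground over background frequency) and a
hypergeometric p modelling the foreground as a draw of its size from the
background pool.  `N` bases are excluded from denominators.

## The simulator

`sim_config()` / `simulate_annotation()` / `simulate_counts()` /
`simulate_reads()` generate a fully self-contained study with known
ground truth.  The defaults define the package's reference synthetic
study, chosen once as a desk-scale analogue of a replicated plant
RNA-seq experiment:

* 300 genes on one chromosome, 3–6 exons of 80–300 nt, introns of
  60–200 nt, 5% monoexonic genes; isoform-structure mix 40% none /
  30% IR / 10% each ES, alt5, alt3 (intron retention dominates annotated
  plant AS events, hence the IR-heavy mix);
* two genotypes × 3 replicates, common NB dispersion $\phi = 0.1$
  (typical for laboratory replicates);
* all primary-isoform introns carry GT..AG ends, with donor windows
  drawn from a configurable categorical model approximating the plant
  consensus (AAG|GTAAGT); a depletion hook weakens chosen positions for
  splice-site experiments, redistributing the removed mass so the
  depleted base's frequency equals the depletion factor exactly;
* sequencing depth is anchored on the *analyzed* bins: the mean expected
  count over AS- and intron-bins is `reads_per_bin` (default 50), which
  puts exon bins proportionally deeper.  Baseline intron density is 20%
  of exonic density — an unspliced/pre-mRNA background level that makes
  constitutive introns measurable without dominating the library;
* 30 injected intron-retention events at a target log2 SIR of +1.5, one
  per gene, placed in introns whose baseline expected count clears the
  mean-count filter with margin (≥ 8 expected reads), so that recovery
  experiments measure detection power rather than filter attrition.
  The injection multiplies the intron bin's expected count by the factor
  that achieves the requested SIR *exactly in expectation*, solving for
  the induced change in gene density; a target that would push the SI
  above 1 is reported as an error naming the bin.

Counts are drawn as a gene-level NB total thinned multinomially over the
gene's bins (weights = bin length × isoform inclusion), so bin margins
are NB with the same dispersion and the gene count equals the sum of its
bin counts.  Read simulation samples reads uniformly along transcripts,
maps them through the exon chain to gapped `M`/`N` CIGARs, and writes a
coordinate-sorted indexed BAM; a per-bin ground-truth tally computed by
direct interval arithmetic (independent of the BAM counting path) is
emitted alongside, and the counting module reproduces it exactly.

What the simulator does *not* emulate: sequencing errors, fragment-length
and positional biases, stranded protocols, multimapping ambiguity,
overlapping gene models (unless constructed), trans effects between
genes, and isoform-level expression correlation beyond the two-isoform
structure.  Green recovery tests therefore demonstrate correctness of
the inference machinery under its own model assumptions, not performance
on real libraries.

## Problem sizes and reproducibility

All randomness in the simulator and pipeline flows from explicit integer
seeds; identical inputs and seeds give byte-identical outputs (checked
by checksum in the tests).  The test suite and the acceptance script use
desk-scale problem sizes chosen to exercise every code path in minutes:
1,000 random gene models for the partition oracle, 2,000 features × 20
seeds for null calibration, the 300-gene reference study × 5 seeds for
event recovery, and window sets of 200 versus 2,000 sequences for the
splice-site statistics.  The calibration fixtures for the splice-site
analysis realize their nucleotide model *exactly* (largest-remainder
composition rounding) so that the depletion factor, not sampling noise,
is the fixture's effect size.

## Known limitations

* The common-dispersion model ignores mean–dispersion trends; strongly
  heteroskedastic data would warrant tagwise shrinkage, which is out of
  scope.
* Total-count normalization is biased under heavy asymmetric DE; use the
  TMM option in such designs.
* Bin-level tests on bins of the same gene are not independent (they
  share the gene's expression draw); BH control is over bins, as in the
  underlying analysis design.
* The partition depends entirely on the annotation: unannotated isoforms
  make their AS regions look constitutive, which is precisely why the
  intron-bin analysis reports "novel" retention separately.
* Exact replication of any published count table additionally depends on
  the aligner and annotation release; the package fixes the analysis
  contract, not the upstream mapping.
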