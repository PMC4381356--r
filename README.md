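# binsplice

Bin-based analysis of differential gene expression and alternative
splicing from replicated RNA-seq designs, with first-class detection of
**novel intron retention**.

## What it does, and for whom

Multi-isoform annotations make per-exon expression ambiguous.
`binsplice` flattens each gene into *bins* — maximal subgenic intervals
within which every isoform has uniform exon/intron status — classified
as exon-bins, intron-bins, or AS-bins (regions directly involved in
annotated alternative splicing: exon skipping, alternative 5′/3′ sites,
intron retention, or composite "multiple" events). Unlike exon-centric
differential-usage methods, *introns are kept as bins*, so changes in
constitutive introns (novel retention events) are directly measurable.

The intended user is a genomicist with a genome FASTA, a GFF3/GTF
annotation, and coordinate-sorted indexed BAMs for a genotype × replicate
design (e.g. wild type vs mutants), who wants, per contrast:

* differential gene expression (NB conditional exact test, common
  dispersion φ with Var = μ + φμ², BH FDR);
* differential bin usage via the **Splicing Index**
  `SI = bin read density / gene read density` and the
  **Splicing Index Ratio** `SIR = SI_mutant / SI_wildtype`, with the
  filter cascade (no monoexonic genes; bin mean count ≥ 5 per condition;
  gene density > 0.05 in all genotypes; SI > 0.05 in a contrast
  genotype) and the three-way altered call
  `|log2 FC| > 0.58 ∧ FDR < 0.15 ∧ |log2 SIR| > 0.58`;
* representation-factor enrichment `RF = k·N/(n1·n2)` of gene lists
  against user-supplied categories, with hypergeometric tail p-values;
* per-position donor/acceptor splice-site composition of the most
  affected intron-retention events against the genome-wide GT..AG intron
  background, as RF + hypergeometric p per matrix cell.

A self-contained simulator (genome, annotation, NB counts with injected
effects of known log2 SIR, gapped reads as sorted BAM) provides ground
truth for every stage.

All user-facing functions take and return tibbles (or small list objects
with `tidy()`/`glance()`/`autoplot()` methods), so analyses compose with
the pipe.

## Worked example

Simulate the package's reference synthetic study (300 genes, wt vs mut,
3 replicates each, φ = 0.1, 30 intron-retention events injected at
log2 SIR = +1.5), partition, and call differential splicing:

```r
library(binsplice)

cfg  <- sim_config(seed = 42)
sim  <- simulate_annotation(cfg)
bins <- partition_bins(sim$exons)
bin_census(bins)
#> # A tibble: 1 × 11
#>   n_bins n_exon n_intron  n_as  n_es n_alt5 n_alt3  n_ir n_multiple ...
#> 1   2461   1321      973   167    30     35     24    78          0

out <- simulate_counts(bins, cfg)
spl <- differential_splicing(out$counts, c("wt", "mut"))
spl
#> <splicing_result> mut vs wt (phi = 0.107)
#>   AS events tested: 167, altered: 0
#>   intron bins tested: 973, altered: 25

head(dplyr::arrange(spl$intron_retention, fdr), 3)[
  , c("bin_id", "si_ref", "si_test", "log2_fc", "log2_sir", "fdr")]
#>   bin_id    si_ref si_test log2_fc log2_sir         fdr
#> 1 G0295:002  0.133   0.490    2.75     1.88  0.000000220
#> 2 G0007:002  0.166   0.538    2.17     1.69  0.0000850
#> 3 G0040:004  0.185   0.513    2.14     1.47  0.0000850
```

Reading the output: the transcriptome flattens into 2,461 bins (1,321
exonic, 973 intronic, 167 AS). The fitted common dispersion (0.107) is
close to the generative value 0.1. The top intron bin `G0295:002` has
SI rising from 0.13 (wild type) to 0.49 (mutant) — a log2 SIR of 1.88 —
with a bin-density log2 fold change of 2.75 at FDR 2.2e-7: a called
intron-retention gain. Checking against the simulator's truth table:

```r
inj    <- out$truth$bin_id[out$truth$injected]
called <- spl$intron_retention$bin_id[spl$intron_retention$altered]
sum(called %in% inj); sum(!called %in% inj)
#> recovered 25 of 30 injected events; 0 false calls
```

With real data, replace the simulator with
`read_annotation()` → `partition_bins()` → `count_reads()` on your
design table, or drive everything from one YAML config with
`run_pipeline()` (see `?run_config`; a thin command-line wrapper lives
in `inst/cli/binsplice.R`).

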