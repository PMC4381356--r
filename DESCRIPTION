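Package: binsplice
Title: Bin-Based Analysis of Differential Expression and Alternative
    Splicing from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Flattens multi-isoform gene annotations into disjoint exon,
    intron and alternative-splicing bins, counts gapped alignments per bin
    and per gene, and detects differential gene expression and differential
    bin usage with a negative-binomial conditional exact test together with
    a Splicing Index Ratio filter cascade, so that both annotated
    alternative-splicing events and novel intron-retention events can be
    called from replicated RNA-seq designs. Also provides
    representation-factor enrichment of gene lists against user-supplied
    functional categories, position-frequency analysis of donor and
    acceptor splice-site sequences, and a self-contained simulator of
    genomes, annotations, counts and aligned reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
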