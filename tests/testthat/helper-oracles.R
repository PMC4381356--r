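# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately written by routes different from the package
# implementation (density products, per-base brute force, manual step-up).

# --- exact-test oracle: conditional probability of the observed split by
# normalizing products of NB (or Poisson) group-sum densities.  Any mu > 0
# gives the same conditional distribution; mu is a free check parameter.
oracle_exact_p <- function(sa, sb, na, nb, phi, mu = 3.7) {
  t <- sa + sb
  if (t == 0) return(1)
  x <- 0:t
  if (phi == 0) {
    w <- dpois(x, na * mu) * dpois(t - x, nb * mu)
  } else {
    w <- dnbinom(x, size = na / phi, mu = na * mu) *
      dnbinom(t - x, size = nb / phi, mu = nb * mu)
  }
  w <- w / sum(w)
  sum(w[w <= w[sa + 1] * (1 + 1e-10)])
}

# --- Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# --- hypergeometric tail by direct combinatorial summation
oracle_hyper_tail <- function(k, n1, n2, N, direction) {
  pmf <- function(x) {
    exp(lchoose(n2, x) + lchoose(N - n2, n1 - x) - lchoose(N, n1))
  }
  xs <- max(0, n1 + n2 - N):min(n1, n2)
  if (direction == "over") sum(pmf(xs[xs >= k])) else sum(pmf(xs[xs <= k]))
}

# --- random multi-isoform gene models for the partition oracle.
# Boundaries are drawn on a grid; each transcript labels the intervals of
# a random sub-span exon/intron and is trimmed to start and end exonic.
random_gene_model <- function(gene_id) {
  n_bound <- sample(3:8, 1)
  bounds <- sort(sample(seq(0, 2000, by = 10), n_bound))
  n_tx <- sample(1:4, 1)
  rows <- list()
  for (t in seq_len(n_tx)) {
    repeat {
      lab <- sample(c("exon", "intron"), n_bound - 1, replace = TRUE)
      exon_iv <- which(lab == "exon")
      if (length(exon_iv) > 0) break
    }
    lo <- min(exon_iv); hi <- max(exon_iv)
    # merge consecutive exon intervals into exons
    st <- integer(0); en <- integer(0)
    i <- lo
    while (i <= hi) {
      if (lab[i] == "exon") {
        j <- i
        while (j < hi && lab[j + 1] == "exon") j <- j + 1
        st <- c(st, bounds[i]); en <- c(en, bounds[j + 1])
        i <- j + 1
      } else i <- i + 1
    }
    rows[[t]] <- tibble::tibble(
      gene_id = gene_id, transcript_id = paste0(gene_id, ".", t),
      chrom = "chrO", start = st, end = en, strand = "+"
    )
  }
  dplyr::bind_rows(rows)
}

# --- per-base classification by brute force: each base polls every
# transcript whose span contains it
oracle_base_kinds <- function(exons) {
  span <- c(min(exons$start), max(exons$end))
  tx <- split(exons, exons$transcript_id)
  vapply(seq(span[1], span[2] - 1), function(p) {
    st <- vapply(tx, function(d) {
      if (p < min(d$start) || p >= max(d$end)) return(NA_character_)
      if (any(p >= d$start & p < d$end)) "exon" else "intron"
    }, "")
    st <- st[!is.na(st)]
    if (length(st) == 0) "intron"
    else if (all(st == "exon")) "exon"
    else if (all(st == "intron")) "intron"
    else "AS"
  }, "")
}

# --- tiny splice_counts builder with deterministic matrices
make_counts <- function(bin_counts, bins, genotypes, n_reps = 2,
                        lib_sizes = NULL) {
  design <- tibble::tibble(
    sample_id = colnames(bin_counts),
    genotype = rep(genotypes, each = n_reps),
    replicate = rep(seq_len(n_reps), length(genotypes))
  )
  gene_counts <- rowsum(bin_counts, bins$gene_id[match(rownames(bin_counts),
                                                       bins$bin_id)])
  splice_counts(bin_counts, gene_counts, bins, design, lib_sizes = lib_sizes)
}

# --- window sets realizing a per-position composition exactly (largest-
# remainder rounding, columnwise shuffle); +1/+2 fixed to GT
composition_windows <- function(n, model, seed) {
  set.seed(seed)
  col <- function(p) {
    k <- floor(model[, p] * n)
    rem <- n - sum(k)
    if (rem > 0) {
      bump <- order(model[, p] * n - k, decreasing = TRUE)[seq_len(rem)]
      k[bump] <- k[bump] + 1
    }
    sample(rep(rownames(model), times = k))
  }
  paste0(col("-3"), col("-2"), col("-1"), "GT",
         col("+3"), col("+4"), col("+5"), col("+6"))
}

# --- hand-written SAM -> sorted+indexed BAM for counting tests
write_test_bam <- function(reads, bam_path, chrom = "chr1", chrom_len = 5000L) {
  # reads: data.frame(qname, flag, pos1 (1-based), cigar)
  sam <- tempfile(fileext = ".sam")
  rl <- vapply(reads$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIS=X]", cg))[[1]]
    sum(as.integer(sub("[MIS=X]", "", ops[grepl("[MS=X]$", ops)])))
  }, 0L)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
    sprintf("%s\t%d\t%s\t%d\t50\t%s\t*\t0\t0\t%s\t%s",
            reads$qname, reads$flag, chrom, reads$pos1, reads$cigar,
            strrep("A", rl), strrep("I", rl))
  ), sam)
  tmp <- Rsamtools::asBam(sam, sub("\\.bam$", "_u", bam_path),
                          overwrite = TRUE, indexDestination = FALSE)
  Rsamtools::sortBam(tmp, sub("\\.bam$", "", bam_path))
  Rsamtools::indexBam(bam_path)
  unlink(c(sam, tmp))
  bam_path
}

toy_bins <- function() {
  gff <- system.file("extdata", "toy_genes.gff3", package = "binsplice")
  partition_bins(read_annotation(gff))
}
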