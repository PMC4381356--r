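# Self-contained simulator: genome + annotation with controlled isoform
# structures and splice-site composition, NB-distributed counts with
# injected differential-splicing effects, and gapped aligned reads.

#' Default donor-site nucleotide model
#'
#' Per-position categorical probabilities for the donor window bases that
#' are free to vary (positions -3..-1 exonic and +3..+6 intronic; +1/+2
#' are fixed to GT).  The default approximates the plant donor consensus
#' (AAG | GTAAGT).  Rows A, C, G, T; columns named by position label.
#'
#' @param deplete Optional named list, e.g. `list("-2" = c(A = 0.5))`,
#'   multiplying the probability of the named base at the named position
#'   by the given factor; the removed mass is redistributed over the
#'   remaining bases, so the depleted base's frequency (and hence its
#'   representation factor against the undepleted model) equals the
#'   factor exactly.  Used to build weakened-site foreground sets.
#' @return A 4 x 7 probability matrix.
#' @export
donor_site_model <- function(deplete = NULL) {
  m <- cbind(
    "-3" = c(A = 0.45, C = 0.15, G = 0.20, T = 0.20),
    "-2" = c(A = 0.60, C = 0.10, G = 0.15, T = 0.15),
    "-1" = c(A = 0.10, C = 0.10, G = 0.70, T = 0.10),
    "+3" = c(A = 0.60, C = 0.05, G = 0.10, T = 0.25),
    "+4" = c(A = 0.70, C = 0.05, G = 0.10, T = 0.15),
    "+5" = c(A = 0.10, C = 0.05, G = 0.60, T = 0.25),
    "+6" = c(A = 0.15, C = 0.10, G = 0.15, T = 0.60)
  )
  if (!is.null(deplete)) {
    for (pos in names(deplete)) {
      fac <- deplete[[pos]]
      hit <- names(fac)
      others <- setdiff(rownames(m), hit)
      removed <- sum(m[hit, pos] * (1 - fac))
      m[hit, pos] <- m[hit, pos] * fac
      m[others, pos] <- m[others, pos] * (1 + removed / sum(m[others, pos]))
    }
  }
  m
}

#' Simulation configuration
#'
#' Bundles and validates the generative parameters.  The defaults define
#' the package's reference synthetic study: 300 genes, two genotypes with
#' 3 replicates each, common NB dispersion 0.1, a mean exon-bin depth of
#' about 50 reads, and 30 injected intron-retention events at
#' |log2 SIR| = 1.5 in the test genotype.
#'
#' @param n_genes Number of genes.
#' @param genotypes Genotype labels; the first is the reference.
#' @param n_reps Replicates per genotype.
#' @param phi Common NB dispersion (`Var = mu + phi mu^2`).
#' @param reads_per_bin Target mean read count over the bins the splicing
#'   analysis tests (AS and intron bins); exon bins are correspondingly
#'   deeper by the inverse of their inclusion-weighted length share.
#' @param structure_mix Named fractions of genes carrying each annotated
#'   isoform structure (`none`, `ES`, `IR`, `alt5`, `alt3`); must sum to 1.
#' @param exon_range,intron_range Length ranges (nt).
#' @param n_exons_range Exons per gene (multi-exon genes).
#' @param monoexonic_frac Fraction of single-exon genes.
#' @param minor_frac Usage fraction of the minor (event) isoform.
#' @param ir_baseline Baseline intron read density relative to the exonic
#'   density (unspliced background, identical in all genotypes).
#' @param n_ir_events Number of injected novel intron-retention events.
#' @param ir_log2_sir Target log2 Splicing Index Ratio of injected events.
#' @param n_de_genes Number of injected differentially expressed genes.
#' @param de_log2_fc Target log2 fold change of injected DE genes.
#' @param read_length Read length for [simulate_reads()].
#' @param donor_model Donor-site model from [donor_site_model()].
#' @param intergenic Gap between consecutive genes (nt).
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300L,
                       genotypes = c("wt", "mut"),
                       n_reps = 3L,
                       phi = 0.1,
                       reads_per_bin = 50,
                       structure_mix = c(none = 0.4, ES = 0.1, IR = 0.3,
                                         alt5 = 0.1, alt3 = 0.1),
                       exon_range = c(80L, 300L),
                       intron_range = c(60L, 200L),
                       n_exons_range = c(3L, 6L),
                       monoexonic_frac = 0.05,
                       minor_frac = 0.3,
                       ir_baseline = 0.2,
                       n_ir_events = 30L,
                       ir_log2_sir = 1.5,
                       n_de_genes = 0L,
                       de_log2_fc = 2,
                       read_length = 100L,
                       donor_model = donor_site_model(),
                       intergenic = 500L,
                       seed) {
  if (missing(seed)) abort("a seed is mandatory in sim_config()")
  if (abs(sum(structure_mix) - 1) > 1e-8) abort("structure_mix must sum to 1")
  if (!all(names(structure_mix) %in% c("none", "ES", "IR", "alt5", "alt3"))) {
    abort("structure_mix names must be none/ES/IR/alt5/alt3")
  }
  stopifnot_scalar_number(phi, "phi", min = 0)
  stopifnot_scalar_number(reads_per_bin, "reads_per_bin", min = 0)
  if (!is.finite(ir_log2_sir) || !is.finite(de_log2_fc)) {
    abort("effect magnitudes must be finite")
  }
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# draw one intron sequence of length len: GT..AG terminal dinucleotides,
# positions +3..+6 from the donor model, rest uniform
intron_seq <- function(len, model) {
  stopifnot(len >= 8L)
  body_len <- len - 2L - 4L - 2L
  plus36 <- vapply(c("+3", "+4", "+5", "+6"), function(p) {
    sample(rownames(model), 1L, prob = model[, p])
  }, "")
  paste0("GT", paste(plus36, collapse = ""), random_dna(body_len), "AG")
}

# last three exonic bases before a donor site, from the model
donor_exon_tail <- function(model) {
  paste(vapply(c("-3", "-2", "-1"), function(p) {
    sample(rownames(model), 1L, prob = model[, p])
  }, ""), collapse = "")
}

#' Generate a genome and annotation with known structure
#'
#' Lays out non-overlapping genes on one chromosome, each with exons and
#' GT..AG introns whose donor windows follow the configured nucleotide
#' model.  Genes are assigned isoform structures per `structure_mix`: a
#' primary transcript using all exons plus, where applicable, a second
#' isoform realizing an exon-skipping, intron-retention, or alternative
#' 5'/3' splice-site event.  Byte-identical output under the same seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_annotation`: `genome`
#'   ([Biostrings::DNAStringSet]), `exons` (exon table as from
#'   [read_annotation()]), `gene_truth` (tibble gene_id, structure,
#'   strand), and `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n <- config$n_genes
  structures <- sample(names(config$structure_mix), n, replace = TRUE,
                       prob = config$structure_mix)
  mono <- runif(n) < config$monoexonic_frac
  structures[mono] <- "none"
  strands <- sample(c("+", "-"), n, replace = TRUE)

  chrom <- "chr1"
  cursor <- config$intergenic
  seq_parts <- list(random_dna(config$intergenic))
  exon_rows <- vector("list", n)
  truth <- vector("list", n)

  for (g in seq_len(n)) {
    gid <- sprintf("G%04d", g)
    n_ex <- if (mono[g]) 1L else
      sample(seq(config$n_exons_range[1L], config$n_exons_range[2L]), 1L)
    ex_len <- sample(seq(config$exon_range[1L], config$exon_range[2L]),
                     n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) {
      sample(seq(config$intron_range[1L], config$intron_range[2L]),
             n_ex - 1L, replace = TRUE)
    } else integer(0)

    # assemble gene sequence; donor windows follow the model on the
    # transcribed strand (genes on "-" get the reverse complement)
    parts <- character(0)
    ex_start <- integer(n_ex)
    pos <- 0L
    for (i in seq_len(n_ex)) {
      ex <- random_dna(ex_len[i])
      if (i < n_ex) {
        tail3 <- donor_exon_tail(config$donor_model)
        substr(ex, ex_len[i] - 2L, ex_len[i]) <- tail3
      }
      ex_start[i] <- pos
      parts <- c(parts, ex)
      pos <- pos + ex_len[i]
      if (i < n_ex) {
        parts <- c(parts, intron_seq(in_len[i], config$donor_model))
        pos <- pos + in_len[i]
      }
    }
    gene_seq <- paste(parts, collapse = "")
    if (strands[g] == "-") gene_seq <- revcomp(gene_seq)

    # exon coordinates on the genome (gene laid down left-to-right; for
    # "-" genes the transcribed exon order is reversed by the revcomp)
    glen <- nchar(gene_seq)
    if (strands[g] == "+") {
      starts <- cursor + ex_start
      ends <- starts + ex_len
    } else {
      starts <- cursor + glen - (ex_start + ex_len)
      ends <- starts + ex_len
      ord <- order(starts)
      starts <- starts[ord]; ends <- ends[ord]
    }

    tx1 <- tibble(gene_id = gid, transcript_id = paste0(gid, ".1"),
                  chrom = chrom, start = starts, end = ends,
                  strand = strands[g])
    tx2 <- make_event_isoform(tx1, structures[g], config)
    if (is.null(tx2)) structures[g] <- "none"  # event infeasible for this gene
    exon_rows[[g]] <- bind_rows(tx1, tx2)
    truth[[g]] <- tibble(gene_id = gid, structure = structures[g],
                         strand = strands[g], n_exons = n_ex)

    seq_parts <- c(seq_parts, gene_seq, random_dna(config$intergenic))
    cursor <- cursor + glen + config$intergenic
  }

  genome <- Biostrings::DNAStringSet(setNames(paste(
    unlist(seq_parts), collapse = ""), chrom))
  structure(
    list(genome = genome, exons = list_rbind(exon_rows),
         gene_truth = list_rbind(truth), config = config),
    class = "sim_annotation"
  )
}

# build the second isoform realizing the requested AS structure; returns
# NULL for "none".  Shifts for alt5/alt3 stay clear of the GT/AG signals.
make_event_isoform <- function(tx1, structure, config) {
  if (structure == "none" || nrow(tx1) < 2L) return(NULL)
  d <- tx1
  d$transcript_id <- paste0(d$gene_id, ".2")
  n_ex <- nrow(d)
  plus <- d$strand[1L] == "+"
  mid <- if (n_ex >= 3L) 2L:(n_ex - 1L) else integer(0)

  if (structure == "ES") {
    if (length(mid) == 0L) return(NULL)
    drop <- sample(mid, 1L)
    return(d[-drop, , drop = FALSE])
  }
  if (structure == "IR") {
    i <- sample(seq_len(n_ex - 1L), 1L)   # retain intron i: merge exons i,i+1
    d$end[i] <- d$end[i + 1L]
    return(d[-(i + 1L), , drop = FALSE])
  }
  # alternative donor (alt5) / acceptor (alt3) on the transcribed strand
  i <- sample(seq_len(n_ex - 1L), 1L)     # intron between exon i and i+1
  intron_len <- d$start[i + 1L] - d$end[i]
  shift <- min(30L, max(10L, intron_len %/% 4L))
  if (intron_len - shift < 10L) return(NULL)
  if (structure == "alt5") {
    # donor moves into the intron: extend the upstream exon (5' side)
    if (plus) d$end[i] <- d$end[i] + shift
    else d$start[i + 1L] <- d$start[i + 1L] - shift
  } else {
    # acceptor moves into the intron: extend the downstream exon (3' side)
    if (plus) d$start[i + 1L] <- d$start[i + 1L] - shift
    else d$end[i] <- d$end[i] + shift
  }
  d
}

#' Write a simulated annotation to FASTA and GFF3
#'
#' @param sim A `sim_annotation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths (`fasta`, `gff3`,
#'   `truth`).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gff3 <- file.path(dir, "annotation.gff3")
  truth <- file.path(dir, "gene_truth.tsv")
  Biostrings::writeXStringSet(sim$genome, fasta)

  ex <- sim$exons
  lines <- c("##gff-version 3")
  for (gid in unique(ex$gene_id)) {
    gx <- ex[ex$gene_id == gid, , drop = FALSE]
    g1 <- sprintf("%s\tbinsplice\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  gx$chrom[1L], min(gx$start) + 1L, max(gx$end),
                  gx$strand[1L], gid)
    tx_lines <- character(0)
    for (tid in unique(gx$transcript_id)) {
      tx <- gx[gx$transcript_id == tid, , drop = FALSE]
      tx_lines <- c(tx_lines,
        sprintf("%s\tbinsplice\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                tx$chrom[1L], min(tx$start) + 1L, max(tx$end),
                tx$strand[1L], tid, gid),
        sprintf("%s\tbinsplice\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                tx$chrom, tx$start + 1L, tx$end, tx$strand, tid))
    }
    lines <- c(lines, g1, tx_lines)
  }
  writeLines(lines, gff3)
  readr::write_tsv(sim$gene_truth, truth)
  invisible(list(fasta = fasta, gff3 = gff3, truth = truth))
}

#' Simulate bin and gene counts with injected splicing effects
#'
#' Per replicate, a gene-level count is drawn as NB(mu_g, phi) and
#' distributed over the gene's bins by multinomial allocation with weights
#' proportional to bin length times isoform inclusion (exon bins weight 1,
#' AS bins the minor-isoform usage, intron bins the baseline retention
#' level), so bin margins are NB with the same dispersion.  Injected
#' intron-retention events multiply the target intron bin's weight in the
#' test genotype by the factor that achieves the requested log2 Splicing
#' Index Ratio exactly in expectation, accounting for the induced change
#' in gene density; an unreachable target (SI above 1) is an error.
#' Injected DE genes scale all bin weights of the gene.
#'
#' @param bins Bin table from [partition_bins()] over the simulated
#'   annotation.
#' @param config The [sim_config()] used to generate the annotation.
#' @param seed Seed for the count noise; defaults to `config$seed + 1`.
#' @return A list: `counts` (a [splice_counts()] object), `truth` (tibble
#'   `bin_id`, `gene_id`, `injected`, `true_log2_sir`) and `gene_truth`
#'   (tibble `gene_id`, `de`, `true_log2_fc`).
#' @export
simulate_counts <- function(bins, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)

  design <- tibble(
    sample_id = paste0(rep(config$genotypes, each = config$n_reps), "_",
                       rep(seq_len(config$n_reps), length(config$genotypes))),
    genotype = rep(config$genotypes, each = config$n_reps),
    replicate = rep(seq_len(config$n_reps), length(config$genotypes))
  )
  ref <- config$genotypes[1L]
  alt <- config$genotypes[-1L]

  usable <- bins[!bins$ambiguous, , drop = FALSE]
  # per-bin inclusion weight (relative read density)
  incl <- dplyr::case_when(
    usable$kind == "exon" ~ 1,
    usable$kind == "AS" & usable$event_class == "IR" ~ config$minor_frac,
    usable$kind == "AS" ~ config$minor_frac +
      (1 - config$minor_frac) * 0,  # minor isoform carries the AS region
    usable$kind == "intron" ~ config$ir_baseline
  )
  # AS regions other than IR are exonic in exactly one isoform
  incl[usable$kind == "AS" & usable$event_class != "IR"] <- config$minor_frac
  w0 <- usable$length * incl

  genes <- unique(usable$gene_id)
  gene_of <- usable$gene_id
  exonic_len <- tapply(usable$length[usable$kind %in% c("exon", "AS")],
                       gene_of[usable$kind %in% c("exon", "AS")], sum)

  # depth anchored on the analyzed bins: the mean expected count over AS
  # and intron bins equals reads_per_bin
  tested_kind <- usable$kind %in% c("AS", "intron")
  denom <- if (any(tested_kind)) mean(w0[tested_kind]) else mean(w0)
  depth_per_nt <- if (denom > 0) config$reads_per_bin / denom else 0
  exp_count0 <- w0 * depth_per_nt
  # inject only into introns whose baseline expected count clears the
  # bin-count filter (mean >= 5) with margin, so recovery measures
  # detection power rather than filter attrition
  cand <- which(usable$kind == "intron" & exp_count0 >= 8)
  cand <- cand[!duplicated(gene_of[cand])]          # one event per gene
  n_ir <- min(config$n_ir_events, length(cand))
  ir_idx <- if (n_ir > 0L) sort(sample(cand, n_ir)) else integer(0)

  de_pool <- setdiff(genes, gene_of[ir_idx])
  n_de <- min(config$n_de_genes, length(de_pool))
  de_genes <- if (n_de > 0L) sort(sample(de_pool, n_de)) else character(0)

  # expected counts per genotype
  w <- matrix(rep(w0, length(config$genotypes)), ncol = length(config$genotypes),
              dimnames = list(usable$bin_id, config$genotypes))
  true_sir <- setNames(rep(0, nrow(usable)), usable$bin_id)
  rho <- 2^config$ir_log2_sir
  for (i in ir_idx) {
    g <- gene_of[i]
    rows <- which(gene_of == g)
    Cg <- sum(w0[rows])      # expected gene total (arbitrary scale)
    cb <- w0[i]
    denom <- Cg - rho * cb
    if (denom <= 0) {
      abort(paste0("target SIR unreachable for bin ", usable$bin_id[i],
                   " (SI would exceed 1)"))
    }
    f <- rho * (Cg - cb) / denom
    for (a in alt) w[i, a] <- w0[i] * f
    true_sir[i] <- config$ir_log2_sir
  }
  for (g in de_genes) {
    rows <- which(gene_of == g)
    for (a in alt) w[rows, a] <- w[rows, a] * 2^config$de_log2_fc
  }

  # draw counts: gene NB total, multinomial split over bins
  bin_mat <- matrix(0L, nrow = nrow(usable), ncol = nrow(design),
                    dimnames = list(usable$bin_id, design$sample_id))
  for (s in seq_len(nrow(design))) {
    gt <- design$genotype[s]
    for (g in genes) {
      rows <- which(gene_of == g)
      mu <- sum(w[rows, gt]) * depth_per_nt
      total <- if (config$phi > 0) {
        rnbinom(1L, mu = mu, size = 1 / config$phi)
      } else {
        rpois(1L, mu)
      }
      if (total > 0L) {
        bin_mat[rows, s] <- as.integer(
          rmultinom(1L, total, prob = w[rows, gt]))
      }
    }
  }
  gene_mat <- rowsum(bin_mat, gene_of)
  gene_mat <- gene_mat[genes, , drop = FALSE]

  counts <- splice_counts(bin_mat, gene_mat, bins, design)
  truth <- tibble(
    bin_id = usable$bin_id, gene_id = gene_of,
    injected = seq_len(nrow(usable)) %in% ir_idx,
    true_log2_sir = unname(true_sir)
  )
  gene_truth <- tibble(
    gene_id = genes, de = genes %in% de_genes,
    true_log2_fc = if_else(genes %in% de_genes, config$de_log2_fc, 0)
  )
  list(counts = counts, truth = truth, gene_truth = gene_truth)
}

#' Simulate gapped reads and write a sorted, indexed BAM
#'
#' Samples reads uniformly along transcripts (abundance-weighted), maps
#' them through the exon chain to genomic M/N CIGARs, and writes a
#' coordinate-sorted, indexed BAM.  A ground-truth per-bin overlap tally
#' (computed by direct interval arithmetic, independently of the BAM
#' counting path) is returned alongside.
#'
#' @param sim A `sim_annotation`.
#' @param bins Bin table over the simulated annotation.
#' @param n_reads Total reads to draw.
#' @param out_bam Output BAM path (the `.bam` suffix is added if absent).
#' @param abundances Optional named per-transcript weights; defaults to
#'   major/minor isoform usage from the config.
#' @param read_length Read length; transcripts shorter than it are skipped
#'   with a warning.
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return A list: `bam` (path), `truth` (tibble `bin_id`, `count`),
#'   `n_reads` (reads actually written).
#' @export
simulate_reads <- function(sim, bins, n_reads, out_bam,
                           abundances = NULL,
                           read_length = sim$config$read_length,
                           seed = sim$config$seed + 2L) {
  stopifnot(inherits(sim, "sim_annotation"))
  set.seed(seed)
  exons <- sim$exons
  tx_ids <- unique(exons$transcript_id)

  tx_list <- split(exons[, c("gene_id", "start", "end", "strand")],
                   exons$transcript_id)
  tx_list <- lapply(tx_list, function(d) d[order(d$start), , drop = FALSE])
  tx_len <- vapply(tx_list, function(d) sum(d$end - d$start), 0L)

  if (is.null(abundances)) {
    minor <- grepl("\\.2$", tx_ids)
    abundances <- setNames(if_else(minor, sim$config$minor_frac,
                                   1 - sim$config$minor_frac), tx_ids)
    solo <- !sub("\\.[12]$", "", tx_ids) %in%
      sub("\\.[12]$", "", tx_ids[minor])
    abundances[solo] <- 1
  }
  short <- tx_len < read_length
  if (any(short[names(abundances)] & abundances > 0)) {
    warn(paste0(sum(short), " transcript(s) shorter than the read length skipped"))
    abundances[names(which(short))] <- 0
  }
  if (all(abundances == 0)) abort("no transcript long enough to sample reads")

  weights <- abundances[tx_ids] * pmax(tx_len[tx_ids] - read_length + 1L, 0L)
  draw <- sample(tx_ids, n_reads, replace = TRUE, prob = weights)
  offsets <- vapply(draw, function(t) {
    sample.int(tx_len[t] - read_length + 1L, 1L) - 1L
  }, 0L)

  # map transcript interval [o, o+rl) to genomic blocks through the exons
  genome_seq <- sim$genome[[1L]]
  chrom <- names(sim$genome)[1L]
  sam_lines <- character(n_reads)
  usable <- bins[!bins$ambiguous, , drop = FALSE]
  truth_count <- setNames(integer(nrow(usable)), usable$bin_id)
  bins_by_gene <- split(seq_len(nrow(usable)), usable$gene_id)

  for (r in seq_len(n_reads)) {
    t <- draw[r]
    d <- tx_list[[t]]
    o <- offsets[r]
    remaining <- read_length
    blocks <- list()
    cum <- 0L
    for (i in seq_len(nrow(d))) {
      elen <- d$end[i] - d$start[i]
      if (o < cum + elen && remaining > 0L) {
        off_in <- max(0L, o - cum)
        take <- min(elen - off_in, remaining)
        blocks[[length(blocks) + 1L]] <-
          c(d$start[i] + off_in, d$start[i] + off_in + take)
        remaining <- remaining - take
      }
      cum <- cum + elen
      if (remaining == 0L) break
    }
    bm <- do.call(rbind, blocks)
    cigar <- character(0)
    for (i in seq_len(nrow(bm))) {
      if (i > 1L) cigar <- c(cigar, sprintf("%dN", bm[i, 1L] - bm[i - 1L, 2L]))
      cigar <- c(cigar, sprintf("%dM", bm[i, 2L] - bm[i, 1L]))
    }
    seq_read <- paste(vapply(seq_len(nrow(bm)), function(i) {
      as.character(Biostrings::subseq(genome_seq, bm[i, 1L] + 1L, bm[i, 2L]))
    }, ""), collapse = "")
    sam_lines[r] <- paste(
      sprintf("read%06d", r), 0L, chrom, bm[1L, 1L] + 1L, 50L,
      paste(cigar, collapse = ""), "*", 0L, 0L, seq_read,
      strrep("I", read_length), sep = "\t")

    # ground truth by direct interval arithmetic against the gene's bins
    g <- d$gene_id[1L]
    for (bi in bins_by_gene[[g]]) {
      bs <- usable$start[bi]; be <- usable$end[bi]
      hit <- any(bm[, 1L] < be & bm[, 2L] > bs)
      if (hit) truth_count[bi] <- truth_count[bi] + 1L
    }
  }

  if (!grepl("\\.bam$", out_bam)) out_bam <- paste0(out_bam, ".bam")
  sam_path <- sub("\\.bam$", ".sam", out_bam)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, length(genome_seq)),
    sam_lines
  ), sam_path)
  tmp_bam <- Rsamtools::asBam(sam_path, sub("\\.bam$", "_unsorted", out_bam),
                              overwrite = TRUE, indexDestination = FALSE)
  Rsamtools::sortBam(tmp_bam, sub("\\.bam$", "", out_bam))
  Rsamtools::indexBam(out_bam)
  unlink(c(sam_path, tmp_bam))

  list(bam = out_bam,
       truth = tibble(bin_id = names(truth_count), count = unname(truth_count)),
       n_reads = n_reads)
}
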