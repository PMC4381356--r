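# Read counting over bins and genes from coordinate-sorted BAM files.

#' Construct a splice_counts container
#'
#' Bundles the bin- and gene-level count matrices with the bin table,
#' design and library sizes.  Normally produced by [count_reads()] or
#' [simulate_counts()]; exposed so that precomputed matrices can enter the
#' pipeline.
#'
#' @param bin_counts,gene_counts Integer matrices (features x samples) with
#'   rownames and colnames.
#' @param bins Bin table from [partition_bins()].
#' @param design Tibble with columns `sample_id`, `genotype`, `replicate`.
#' @param lib_sizes Named numeric vector of per-sample totals of assigned
#'   reads; defaults to the column sums of `gene_counts`.
#' @return An object of class `splice_counts`.
#' @export
splice_counts <- function(bin_counts, gene_counts, bins, design,
                          lib_sizes = NULL) {
  check_design(design)
  if (is.null(lib_sizes)) lib_sizes <- colSums(gene_counts)
  stopifnot(
    identical(colnames(bin_counts), design$sample_id),
    identical(colnames(gene_counts), design$sample_id),
    all(bin_counts >= 0), all(gene_counts >= 0)
  )
  # exonic length per gene: union of exon- and AS-bins actually counted
  counted <- bins[!bins$ambiguous, , drop = FALSE]
  exonic <- counted |>
    filter(.data$kind %in% c("exon", "AS")) |>
    group_by(.data$gene_id) |>
    summarise(exonic_length = sum(.data$length), .groups = "drop")
  gene_lengths <- setNames(exonic$exonic_length, exonic$gene_id)

  structure(
    list(
      bin_counts = bin_counts,
      gene_counts = gene_counts,
      bins = bins,
      design = design,
      lib_sizes = lib_sizes,
      bin_lengths = setNames(bins$length, bins$bin_id)[rownames(bin_counts)],
      gene_lengths = gene_lengths[rownames(gene_counts)]
    ),
    class = "splice_counts"
  )
}

#' @export
print.splice_counts <- function(x, ...) {
  cat("<splice_counts>\n")
  cat("  bins:   ", nrow(x$bin_counts), " x ", ncol(x$bin_counts), "\n", sep = "")
  cat("  genes:  ", nrow(x$gene_counts), " x ", ncol(x$gene_counts), "\n", sep = "")
  cat("  genotypes: ", paste(unique(x$design$genotype), collapse = ", "), "\n", sep = "")
  cat("  library sizes: ", paste(format(x$lib_sizes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Count reads per bin and per gene
#'
#' A read is assigned to every non-ambiguous bin that any of its aligned
#' (M) segments overlaps by at least one nucleotide; N-gap (skipped)
#' portions do not create overlap, so a junction read spanning an intron
#' bin contributes nothing to it.  The gene count is the number of reads
#' overlapping at least one bin of the gene, counted once per gene.
#' Unmapped, secondary and duplicate-flagged reads are skipped.  Counting
#' is unstranded by default, matching unstranded library protocols.
#'
#' @param bins Bin table from [partition_bins()].
#' @param design Tibble with columns `sample_id`, `bam_path`, `genotype`,
#'   `replicate`.  Each BAM must be coordinate-sorted and indexed.
#' @param stranded If `TRUE`, require read strand to match the bin strand.
#' @param chrom_alias Optional named character vector mapping BAM contig
#'   names to annotation names.
#' @return A [splice_counts()] object.  Samples whose BAM contains no
#'   usable reads are dropped with a warning.
#' @export
count_reads <- function(bins, design, stranded = FALSE, chrom_alias = NULL) {
  check_design(design)
  if (!"bam_path" %in% names(design)) abort("design must have a bam_path column")

  counted <- bins[!bins$ambiguous, , drop = FALSE]
  bin_gr <- GenomicRanges::GRanges(
    counted$chrom,
    IRanges::IRanges(counted$start + 1L, counted$end),
    strand = counted$strand
  )
  genes <- unique(bins$gene_id)

  bin_mat <- matrix(0L, nrow = nrow(counted), ncol = nrow(design),
                    dimnames = list(counted$bin_id, design$sample_id))
  gene_mat <- matrix(0L, nrow = length(genes), ncol = nrow(design),
                     dimnames = list(genes, design$sample_id))
  lib_sizes <- setNames(numeric(nrow(design)), design$sample_id)

  for (i in seq_len(nrow(design))) {
    bam <- design$bam_path[i]
    if (!file.exists(bam)) abort(paste0("BAM not found: ", bam))
    bai <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
    if (!any(file.exists(bai))) abort(paste0("missing BAM index for: ", bam))

    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isDuplicate = FALSE)
    aln <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(flag = flags))
    if (length(aln) == 0L) {
      warn(paste0("no usable reads in ", bam, "; sample ",
                  design$sample_id[i], " dropped"))
      lib_sizes[i] <- NA_real_
      next
    }

    segs <- GenomicAlignments::grglist(aln)  # M segments; N gaps excluded
    if (!is.null(chrom_alias)) {
      lv <- GenomeInfoDb::seqlevels(segs)
      hit <- lv %in% names(chrom_alias)
      lv[hit] <- unname(chrom_alias[lv[hit]])
      GenomeInfoDb::seqlevels(segs) <- lv
    }
    unknown <- setdiff(GenomeInfoDb::seqlevels(segs), unique(bins$chrom))
    if (length(unknown) > 0L) {
      warn(paste0("contig(s) absent from annotation ignored: ",
                  paste(unknown, collapse = ", ")))
    }

    hits <- GenomicRanges::findOverlaps(segs, bin_gr,
                                        ignore.strand = !stranded,
                                        minoverlap = 1L)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    if (length(q) > 0L) {
      bt <- table(s)
      bin_mat[as.integer(names(bt)), i] <- as.integer(bt)
      gpair <- unique(data.frame(read = q, gene = counted$gene_id[s]))
      gt <- table(gpair$gene)
      gene_mat[names(gt), i] <- as.integer(gt)
      lib_sizes[i] <- length(unique(q))
    } else {
      lib_sizes[i] <- 0
    }
  }

  keep <- !is.na(lib_sizes)
  splice_counts(bin_mat[, keep, drop = FALSE],
                gene_mat[, keep, drop = FALSE],
                bins, design[keep, , drop = FALSE],
                lib_sizes[keep])
}

#' Read densities per feature and sample
#'
#' Read density is the read count divided by the feature length, in reads
#' per nucleotide.  Bin density uses the bin length; gene density uses the
#' gene's exonic length (union of its exon- and AS-bins), since gene
#' expression is carried by exonic sequence.
#'
#' @param counts A [splice_counts()] object.
#' @param level `"bin"` or `"gene"`.
#' @return A long tibble: `feature_id`, `sample_id`, `genotype`, `count`,
#'   `length`, `density`.
#' @examples
#' # read_density(counts, "bin") |> dplyr::group_by(feature_id, genotype)
#' @export
read_density <- function(counts, level = c("bin", "gene")) {
  level <- match.arg(level)
  mat <- if (level == "bin") counts$bin_counts else counts$gene_counts
  len <- if (level == "bin") counts$bin_lengths else counts$gene_lengths
  len <- len[rownames(mat)]
  if (any(is.na(len) | len <= 0)) abort("feature with missing or zero length")
  as_tibble(mat, rownames = "feature_id") |>
    pivot_longer(-"feature_id", names_to = "sample_id", values_to = "count") |>
    left_join(select(counts$design, "sample_id", "genotype"), by = "sample_id") |>
    mutate(length = unname(len[.data$feature_id]),
           density = .data$count / .data$length)
}

# genotype-mean density matrices (features x genotypes), used by the
# splicing pipeline; mean density = mean count across replicates / length
density_by_genotype <- function(counts, level = c("bin", "gene"),
                                genotypes = NULL) {
  level <- match.arg(level)
  mat <- if (level == "bin") counts$bin_counts else counts$gene_counts
  len <- if (level == "bin") counts$bin_lengths else counts$gene_lengths
  len <- len[rownames(mat)]
  genotypes <- genotypes %||% unique(counts$design$genotype)
  out <- vapply(genotypes, function(g) {
    row_group_means(mat, samples_of(counts$design, g)) / len
  }, numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(genotypes))
  dimnames(out) <- list(rownames(mat), genotypes)
  out
}

# genotype-mean raw count matrices
count_by_genotype <- function(mat, design, genotypes = NULL) {
  genotypes <- genotypes %||% unique(design$genotype)
  out <- vapply(genotypes, function(g) {
    row_group_means(mat, samples_of(design, g))
  }, numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(genotypes))
  dimnames(out) <- list(rownames(mat), genotypes)
  out
}
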