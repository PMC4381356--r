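# Flattening gene models into disjoint bins and classifying AS events.

#' Flatten one gene into disjoint bins
#'
#' Cuts the gene span at every distinct exon boundary across all isoforms.
#' Each resulting interval is a bin; a bin exonic in every transcript that
#' overlaps it is an exon-bin, intronic in every such transcript an
#' intron-bin, and mixed an AS-bin, whose event class is assigned by
#' [classify_event()].  Transcripts that do not overlap a bin do not vote
#' on its status.
#'
#' @param exons Exon table rows for a single gene (columns as in
#'   [read_annotation()]).
#' @return A tibble of bins: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `kind` (exon/intron/AS), `event_class` (ES/alt5/alt3/IR/multiple/none)
#'   and `length`, tiling the gene span.
#' @export
flatten_gene <- function(exons) {
  gid <- unique(exons$gene_id)
  if (length(gid) != 1L) abort("flatten_gene() expects exons of exactly one gene")
  strand <- exons$strand[1L]
  chrom <- exons$chrom[1L]

  tx <- split(exons[, c("start", "end")], exons$transcript_id)
  tx <- lapply(tx, function(d) d[order(d$start), , drop = FALSE])
  for (d in tx) {
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      abort(paste0("overlapping exons within a transcript of gene ", gid))
    }
  }
  tx_span <- lapply(tx, function(d) c(min(d$start), max(d$end)))

  cuts <- sort(unique(c(exons$start, exons$end)))
  bs <- cuts[-length(cuts)]
  be <- cuts[-1L]
  n <- length(bs)

  # per-transcript exon/intron status at an interval [s,e) known not to
  # straddle any exon boundary of that transcript
  status_at <- function(d, span, pos) {
    # pos: any base inside the interval; returns "exon"/"intron"/NA (outside)
    if (pos < span[1L] || pos >= span[2L]) return(NA_character_)
    if (any(pos >= d$start & pos < d$end)) "exon" else "intron"
  }

  kind <- character(n)
  event <- rep("none", n)
  for (i in seq_len(n)) {
    pos <- bs[i]
    st <- vapply(seq_along(tx),
                 function(j) status_at(tx[[j]], tx_span[[j]], pos), "")
    ex_tx <- names(tx)[!is.na(st) & st == "exon"]
    in_tx <- names(tx)[!is.na(st) & st == "intron"]
    if (length(ex_tx) == 0L && length(in_tx) == 0L) {
      kind[i] <- "intron"   # gap covered by no transcript span
    } else if (length(in_tx) == 0L) {
      kind[i] <- "exon"
    } else if (length(ex_tx) == 0L) {
      kind[i] <- "intron"
    } else {
      kind[i] <- "AS"
      event[i] <- classify_event(bs[i], be[i], tx[in_tx],
                                 tx_span[in_tx], strand)
    }
  }

  tibble(
    gene_id = gid, chrom = chrom, start = bs, end = be, strand = strand,
    kind = kind, event_class = event, length = be - bs
  )
}

#' Classify an alternatively spliced bin
#'
#' For each transcript in which the bin is intronic, the exon/intron status
#' of the bases immediately flanking the bin in that transcript determines
#' the event topology:
#' `(intron, intron)` is a skipped exon (ES); `(exon, exon)` a retained
#' intron (IR); `(exon, intron)` an alternative 5' site on the plus strand
#' (3' on the minus strand); `(intron, exon)` the converse.  If different
#' intronic transcripts disagree, or a flank falls outside a transcript
#' span, the bin is classified `multiple`.
#'
#' @param bin_start,bin_end Bin interval (0-based, half-open).
#' @param intronic_tx List of exon data frames (`start`, `end`) for the
#'   transcripts in which the bin is intronic.
#' @param tx_spans List of `c(start, end)` spans matching `intronic_tx`.
#' @param strand `"+"` or `"-"`.
#' @return One of `"ES"`, `"alt5"`, `"alt3"`, `"IR"`, `"multiple"`.
#' @export
classify_event <- function(bin_start, bin_end, intronic_tx, tx_spans, strand) {
  if (length(intronic_tx) == 0L) abort("classify_event(): no intronic transcript")
  one <- function(d, span) {
    lpos <- bin_start - 1L
    rpos <- bin_end
    if (lpos < span[1L] || rpos >= span[2L]) return("multiple")
    lst <- if (any(lpos >= d$start & lpos < d$end)) "exon" else "intron"
    rst <- if (any(rpos >= d$start & rpos < d$end)) "exon" else "intron"
    if (lst == "intron" && rst == "intron") return("ES")
    if (lst == "exon" && rst == "exon") return("IR")
    if (lst == "exon" && rst == "intron") {
      return(if (strand == "+") "alt5" else "alt3")
    }
    if (strand == "+") "alt3" else "alt5"
  }
  classes <- unique(vapply(seq_along(intronic_tx),
                           function(j) one(intronic_tx[[j]], tx_spans[[j]]), ""))
  if (length(classes) > 1L || "multiple" %in% classes) "multiple" else classes
}

#' Partition a transcriptome into bins
#'
#' Applies [flatten_gene()] to every gene of an exon table, numbers the
#' bins per gene in coordinate order, flags bins that overlap a different
#' gene on either strand as `ambiguous` (such bins are excluded from read
#' counting by default), and flags genes that flatten to a single exon bin
#' as `monoexonic`.
#'
#' @param exons Exon table from [read_annotation()].
#' @return A tibble of bins with columns `bin_id` (`gene_id:index`),
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `kind`, `event_class`,
#'   `length`, `ambiguous`, `monoexonic`.  The census of bin kinds is
#'   available through [bin_census()].
#' @examples
#' gff <- system.file("extdata", "toy_genes.gff3", package = "binsplice")
#' bins <- partition_bins(read_annotation(gff))
#' bin_census(bins)
#' @export
partition_bins <- function(exons) {
  key <- exons |>
    distinct(.data$gene_id, .data$chrom, .data$strand)
  if (anyDuplicated(key$gene_id)) {
    abort("duplicate gene_id with conflicting chromosome/strand in annotation")
  }

  bins <- exons |>
    mutate(.gene = factor(.data$gene_id, levels = unique(.data$gene_id))) |>
    group_by(.data$.gene) |>
    group_split() |>
    map(\(d) flatten_gene(select(d, -".gene"))) |>
    list_rbind() |>
    group_by(.data$gene_id) |>
    mutate(bin_id = sprintf("%s:%03d", .data$gene_id, row_number()),
           monoexonic = n() == 1L) |>
    ungroup()

  # flag bins overlapping the span of another gene (either strand)
  spans <- exons |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  span_gr <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end))
  bin_gr <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  hits <- GenomicRanges::findOverlaps(bin_gr, span_gr, ignore.strand = TRUE)
  other <- bins$gene_id[S4Vectors::queryHits(hits)] !=
    spans$gene_id[S4Vectors::subjectHits(hits)]
  bins$ambiguous <- FALSE
  bins$ambiguous[unique(S4Vectors::queryHits(hits)[other])] <- TRUE

  bins |>
    select("bin_id", "gene_id", "chrom", "start", "end", "strand",
           "kind", "event_class", "length", "ambiguous", "monoexonic")
}

#' Census of a bin table
#'
#' @param bins Bin table from [partition_bins()].
#' @return A one-row tibble: total bins, counts per kind, and counts per
#'   AS event class.
#' @export
bin_census <- function(bins) {
  tibble(
    n_bins = nrow(bins),
    n_exon = sum(bins$kind == "exon"),
    n_intron = sum(bins$kind == "intron"),
    n_as = sum(bins$kind == "AS"),
    n_es = sum(bins$event_class == "ES"),
    n_alt5 = sum(bins$event_class == "alt5"),
    n_alt3 = sum(bins$event_class == "alt3"),
    n_ir = sum(bins$event_class == "IR"),
    n_multiple = sum(bins$event_class == "multiple"),
    n_ambiguous = sum(bins$ambiguous),
    n_monoexonic_genes = n_distinct(bins$gene_id[bins$monoexonic])
  )
}

#' Write a bin table to TSV and BED6
#'
#' The TSV keeps internal 0-based half-open coordinates; the BED file is
#' 0-based half-open by definition, with `name` = bin id and score 0.
#'
#' @param bins Bin table.
#' @param tsv,bed Output paths (either may be `NULL` to skip).
#' @return Invisibly, `bins`.
#' @export
write_bins <- function(bins, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) readr::write_tsv(bins, tsv)
  if (!is.null(bed)) {
    bed_df <- tibble(chrom = bins$chrom, start = bins$start, end = bins$end,
                     name = bins$bin_id, score = 0L, strand = bins$strand)
    readr::write_tsv(bed_df, bed, col_names = FALSE)
  }
  invisible(bins)
}
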