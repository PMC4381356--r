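#' Read a gene annotation into an exon table
#'
#' Parses a GFF3 or GTF annotation and returns one row per exon with its
#' gene and transcript ownership.  File coordinates (1-based, inclusive)
#' are converted to the package-internal convention of 0-based, half-open
#' intervals; all downstream interval arithmetic uses that convention and
#' converts back only when writing browser formats.
#'
#' Both common attribute dialects are understood: GTF `gene_id` /
#' `transcript_id` pairs, and GFF3 `ID` / `Parent` hierarchies
#' (gene -> mRNA/transcript -> exon).  Transcript features without any exon
#' children are skipped with a warning.
#'
#' @param path Path to a GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, ordered by chromosome,
#'   gene start and gene id, and by start within each transcript.
#' @examples
#' gff <- system.file("extdata", "toy_genes.gff3", package = "binsplice")
#' read_annotation(gff)
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) abort(paste0("cannot parse annotation '", path, "': ",
                                     conditionMessage(e)))
  )
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0L) abort(paste0("no exon features in ", path))

  mc <- S4Vectors::mcols(ex)
  if ("transcript_id" %in% names(mc) && !all(is.na(mc$transcript_id))) {
    tx_id <- as.character(mc$transcript_id)
    gene_id <- as.character(mc$gene_id)
  } else if ("Parent" %in% names(mc)) {
    parents <- as(mc$Parent, "CharacterList")
    if (any(lengths(parents) == 0L)) abort("exon feature without Parent attribute")
    tx_id <- unlist(lapply(parents, `[`, 1L), use.names = FALSE)
    # map transcript -> gene through the mRNA/transcript features
    txf <- gr[type %in% c("mRNA", "transcript") |
                grepl("transcript|RNA", type, ignore.case = TRUE)]
    tmc <- S4Vectors::mcols(txf)
    tx_gene <- setNames(
      vapply(as(tmc$Parent, "CharacterList"),
             function(p) if (length(p)) p[[1L]] else NA_character_, ""),
      as.character(tmc$ID)
    )
    gene_id <- unname(tx_gene[tx_id])
    gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]  # orphan transcripts
  } else {
    abort("annotation carries neither transcript_id/gene_id nor ID/Parent attributes")
  }

  exons <- tibble(
    gene_id = gene_id,
    transcript_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,   # 1-based inclusive -> 0-based half-open
    end   = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex))
  )
  exons$strand[!exons$strand %in% c("+", "-")] <- "+"

  # transcripts declared but without exon children
  declared <- gr[type %in% c("mRNA", "transcript")]
  if (length(declared) > 0L) {
    ids <- as.character(S4Vectors::mcols(declared)$ID %||%
                          S4Vectors::mcols(declared)$transcript_id)
    orphan <- setdiff(ids[!is.na(ids)], unique(exons$transcript_id))
    if (length(orphan) > 0L) {
      warn(paste0("skipping ", length(orphan),
                  " transcript(s) without exons: ",
                  paste(head(orphan, 5L), collapse = ", ")))
    }
  }

  gene_order <- exons |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), gstart = min(.data$start),
              .groups = "drop") |>
    arrange(.data$chrom, .data$gstart, .data$gene_id)
  exons |>
    mutate(gene_id = factor(.data$gene_id, levels = gene_order$gene_id)) |>
    arrange(.data$gene_id, .data$transcript_id, .data$start) |>
    mutate(gene_id = as.character(.data$gene_id))
}

#' Summarize gene models from an exon table
#'
#' @param exons Exon table as returned by [read_annotation()].
#' @return A tibble with one row per gene: span, strand, transcript and
#'   exon counts, and a `monoexonic` flag (every transcript has one exon).
#' @export
gene_models <- function(exons) {
  exons |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      span_start = min(.data$start),
      span_end = max(.data$end),
      n_transcripts = n_distinct(.data$transcript_id),
      n_exons = n(),
      monoexonic = all(table(.data$transcript_id) == 1L) &&
        n_distinct(paste(.data$start, .data$end)) == 1L,
      .groups = "drop"
    )
}
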