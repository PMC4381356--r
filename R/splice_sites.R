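# Donor/acceptor splice-site windows and position frequency statistics.

#' Select the most affected intron-retention events
#'
#' Keeps intron-retention records changed at least `fold`-fold
#' (|log2 SIR| >= log2(fold)) at `FDR <= fdr` (both inclusive, unlike the
#' strict altered-bin call).
#'
#' @param records A `splicing_result` or its `intron_retention` tibble
#'   (columns `log2_sir`, `fdr`).
#' @param fold Minimum SI ratio fold change (default 2).
#' @param fdr Maximum FDR (default 0.1).
#' @return The selected records.
#' @export
select_top_events <- function(records, fold = 2, fdr = 0.1) {
  if (inherits(records, "splicing_result")) records <- records$intron_retention
  records |>
    filter(!is.na(.data$log2_sir),
           abs(.data$log2_sir) >= log2(fold), .data$fdr <= !!fdr)
}

#' Partition selected events across two genotype contrasts
#'
#' @param sel_a,sel_b Selections from [select_top_events()] for two
#'   contrasts over the same bin universe.
#' @return A list of bin id vectors: `only_a`, `only_b`, `both`.
#' @export
event_sets <- function(sel_a, sel_b) {
  list(
    only_a = setdiff(sel_a$bin_id, sel_b$bin_id),
    only_b = setdiff(sel_b$bin_id, sel_a$bin_id),
    both = intersect(sel_a$bin_id, sel_b$bin_id)
  )
}

#' Enumerate annotated introns from an exon table
#'
#' Introns are the gaps between consecutive exons within each transcript;
#' duplicates across transcripts are collapsed.
#'
#' @param exons Exon table from [read_annotation()].
#' @return A tibble `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `gene_id`.
#' @export
annotated_introns <- function(exons) {
  exons |>
    arrange(.data$gene_id, .data$transcript_id, .data$start) |>
    group_by(.data$gene_id, .data$transcript_id) |>
    reframe(chrom = .data$chrom[-1L], strand = .data$strand[-1L],
            intron_start = .data$end[-n()], intron_end = .data$start[-1L]) |>
    rename(start = "intron_start", end = "intron_end") |>
    filter(.data$end > .data$start) |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand,
             .keep_all = TRUE) |>
    select("chrom", "start", "end", "strand", "gene_id")
}

#' Keep introns with GT...AG terminal dinucleotides
#'
#' Approximates the major-spliceosome (U2-type) intron set by the terminal
#' dinucleotide rule, strand-corrected.
#'
#' @param introns Intron tibble from [annotated_introns()].
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return The subset of `introns` whose first two intronic bases are GT
#'   and last two AG (on the transcribed strand).
#' @export
gtag_introns <- function(introns, genome) {
  genome <- load_genome(genome)
  ok <- vapply(seq_len(nrow(introns)), function(i) {
    s <- introns$start[i]; e <- introns$end[i]
    if (e - s < 4L) return(FALSE)
    don <- substr_genome(genome, introns$chrom[i], s, s + 2L)
    acc <- substr_genome(genome, introns$chrom[i], e - 2L, e)
    if (introns$strand[i] == "+") {
      don == "GT" && acc == "AG"
    } else {
      revcomp(acc) == "GT" && revcomp(don) == "AG"
    }
  }, TRUE)
  introns[ok, , drop = FALSE]
}

load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!is.null(names(genome))) names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

substr_genome <- function(genome, chrom, start, end) {
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract splice-site windows
#'
#' Donor windows cover `up` exonic bases upstream and `down` intronic
#' bases downstream of the exon|intron boundary (positions `-up..-1`,
#' `+1..+down` in the transcription direction); acceptor windows mirror
#' this at the intron|exon boundary (positions `-down..-1` intronic,
#' `+1..+up` exonic).  Minus-strand windows are reverse-complemented so
#' that all sequences read 5' to 3'.  Windows running off a contig are
#' skipped with a warning.
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param introns Intron tibble (`chrom`, `start`, `end`, `strand`;
#'   0-based half-open).
#' @param site_type `"donor"` or `"acceptor"`.
#' @param up Exonic bases in the window (default 3).
#' @param down Intronic bases in the window (default 10).
#' @return An object of class `site_windows`: list with `seqs`
#'   ([Biostrings::DNAStringSet]), `positions` (labels like `"-2"`,
#'   `"+1"`), `site_type`, `up`, `down`.
#' @export
extract_windows <- function(genome, introns, site_type = c("donor", "acceptor"),
                            up = 3L, down = 10L) {
  site_type <- match.arg(site_type)
  genome <- load_genome(genome)
  missing_chrom <- setdiff(unique(introns$chrom), names(genome))
  if (length(missing_chrom) > 0L) {
    abort(paste0("contig(s) absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  }

  win <- function(chrom, s, e, strand) {
    clen <- length(genome[[chrom]])
    if (site_type == "donor") {
      if (strand == "+") { ws <- s - up; we <- s + down; rc <- FALSE }
      else { ws <- e - down; we <- e + up; rc <- TRUE }
    } else {
      if (strand == "+") { ws <- e - down; we <- e + up; rc <- FALSE }
      else { ws <- s - up; we <- s + down; rc <- TRUE }
    }
    if (ws < 0L || we > clen) return(NA_character_)
    seq <- substr_genome(genome, chrom, ws, we)
    if (rc) revcomp(seq) else seq
  }

  seqs <- vapply(seq_len(nrow(introns)), function(i) {
    win(introns$chrom[i], introns$start[i], introns$end[i], introns$strand[i])
  }, "")
  dropped <- sum(is.na(seqs))
  if (dropped > 0L) {
    warn(paste0(dropped, " window(s) exceeding contig bounds skipped"))
  }
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0L) abort("no windows could be extracted")

  positions <- if (site_type == "donor") {
    c(paste0("-", rev(seq_len(up))), paste0("+", seq_len(down)))
  } else {
    c(paste0("-", rev(seq_len(down))), paste0("+", seq_len(up)))
  }
  structure(
    list(seqs = Biostrings::DNAStringSet(seqs), positions = positions,
         site_type = site_type, up = up, down = down),
    class = "site_windows"
  )
}

#' @export
print.site_windows <- function(x, ...) {
  cat("<site_windows> ", length(x$seqs), " ", x$site_type,
      " windows, positions ", x$positions[1L], "..",
      x$positions[length(x$positions)], "\n", sep = "")
  invisible(x)
}

#' Build site windows directly from sequences
#'
#' Convenience constructor for simulated or externally prepared window
#' sets (all sequences must share one length).
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet].
#' @inheritParams extract_windows
#' @return A `site_windows` object.
#' @export
site_windows <- function(seqs, site_type = c("donor", "acceptor"),
                         up = 3L, down = NULL) {
  site_type <- match.arg(site_type)
  seqs <- Biostrings::DNAStringSet(seqs)
  L <- unique(Biostrings::width(seqs))
  if (length(L) != 1L) abort("all window sequences must have equal length")
  down <- down %||% (L - up)
  if (up + down != L) abort("up + down must equal the window length")
  positions <- if (site_type == "donor") {
    c(paste0("-", rev(seq_len(up))), paste0("+", seq_len(down)))
  } else {
    c(paste0("-", rev(seq_len(down))), paste0("+", seq_len(up)))
  }
  structure(list(seqs = seqs, positions = positions, site_type = site_type,
                 up = up, down = down),
            class = "site_windows")
}

#' Position frequency matrix with representation factors
#'
#' Computes per-position nucleotide counts and frequencies for a
#' foreground window set, compares each cell with the background
#' frequency via the representation factor (foreground frequency /
#' background frequency), and attaches a hypergeometric tail p-value per
#' cell, modelling the foreground as a draw of its size from the
#' background pool (over- or under-representation chosen by the RF).
#' `N` bases are excluded from frequency denominators.
#'
#' @param foreground,background `site_windows` objects of equal window
#'   length (e.g. selected intron-retention donors vs all GT-AG donors).
#' @return A tibble of class `site_matrix`: `position`, `nucleotide`,
#'   `fg_count`, `fg_freq`, `bg_count`, `bg_freq`, `rf`, `direction`, `p`.
#' @export
site_matrix <- function(foreground, background) {
  stopifnot(inherits(foreground, "site_windows"),
            inherits(background, "site_windows"))
  if (length(foreground$seqs) == 0L) abort("empty foreground window set")
  Lf <- unique(Biostrings::width(foreground$seqs))
  Lb <- unique(Biostrings::width(background$seqs))
  if (!identical(Lf, Lb)) abort("foreground and background window lengths differ")

  cm <- function(w) {
    m <- Biostrings::consensusMatrix(w$seqs)
    m[intersect(c("A", "C", "G", "T"), rownames(m)), , drop = FALSE] |>
      (\(mm) {
        full <- matrix(0L, 4L, ncol(mm), dimnames = list(c("A", "C", "G", "T"), NULL))
        full[rownames(mm), ] <- mm
        full
      })()
  }
  fg <- cm(foreground)
  bg <- cm(background)
  fg_n <- colSums(fg)  # non-N depth per position
  bg_n <- colSums(bg)

  nucs <- c("A", "C", "G", "T")
  out <- map(seq_len(Lf), function(j) {
    map(nucs, function(b) {
      k <- fg[b, j]; K <- bg[b, j]
      fg_freq <- if (fg_n[j] > 0) k / fg_n[j] else NA_real_
      bg_freq <- if (bg_n[j] > 0) K / bg_n[j] else NA_real_
      rf <- if (!is.na(bg_freq) && bg_freq > 0) fg_freq / bg_freq else NA_real_
      over <- is.na(rf) || rf >= 1
      p <- if (is.na(rf)) {
        NA_real_
      } else if (over) {
        phyper(k - 1, K, bg_n[j] - K, fg_n[j], lower.tail = FALSE)
      } else {
        phyper(k, K, bg_n[j] - K, fg_n[j], lower.tail = TRUE)
      }
      tibble(position = foreground$positions[j], nucleotide = b,
             fg_count = unname(k), fg_freq = unname(fg_freq),
             bg_count = unname(K), bg_freq = unname(bg_freq),
             rf = unname(rf),
             direction = if (is.na(rf)) NA_character_ else if (over) "over" else "under",
             p = unname(p))
    }) |> list_rbind()
  }) |> list_rbind()

  out$position <- factor(out$position, levels = foreground$positions)
  structure(out, class = c("site_matrix", class(out)),
            site_type = foreground$site_type,
            n_fg = length(foreground$seqs), n_bg = length(background$seqs))
}

#' @export
tidy.site_matrix <- function(x, ...) as_tibble(x)
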