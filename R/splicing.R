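# Bin-level differential splicing: Splicing Index, Splicing Index Ratio,
# the filter cascade, and the exact test applied per bin.

#' Splicing Index
#'
#' The Splicing Index (SI) of a bin in one genotype is the bin read
#' density divided by the gene read density, a length-normalized inclusion
#' measure.  A zero gene density leaves the SI undefined (`NA`); such
#' records are excluded downstream.
#'
#' @param bin_density,gene_density Non-negative densities (reads per nt).
#' @return `bin_density / gene_density`, `NA` where `gene_density == 0`.
#' @export
splicing_index <- function(bin_density, gene_density) {
  if (any(bin_density < 0, na.rm = TRUE) || any(gene_density < 0, na.rm = TRUE)) {
    abort("densities must be non-negative")
  }
  ifelse(gene_density == 0, NA_real_, bin_density / gene_density)
}

#' Log2 Splicing Index Ratio
#'
#' @param si_test,si_ref Splicing Index in the test (mutant) and reference
#'   (wild-type) genotype.  Zero or undefined SIs yield `NA` (the record is
#'   excluded, not an error).
#' @return `log2(si_test / si_ref)`.
#' @export
splicing_index_ratio <- function(si_test, si_ref) {
  ifelse(is.na(si_test) | is.na(si_ref) | si_test <= 0 | si_ref <= 0,
         NA_real_, log2(si_test / si_ref))
}

#' Bin filter cascade for the splicing analysis
#'
#' Applies, in order: drop ambiguous bins (overlapping another gene); drop
#' bins of monoexonic genes; drop bins whose mean raw count is below
#' `min_count` in any condition; drop bins of genes whose read density is
#' at or below `min_gene_density` in any genotype; drop bins whose
#' Splicing Index is at or below `min_si` in every contrast genotype.
#'
#' @param counts A [splice_counts()] object.
#' @param contrast Two genotypes whose SIs satisfy the SI rule; defaults
#'   to all genotypes of the design.
#' @param min_count Mean raw count required in every condition (default 5).
#' @param min_gene_density Gene read density required in all genotypes
#'   (default 0.05 reads/nt, strict `>`).
#' @param min_si Splicing Index required in at least one contrast genotype
#'   (default 0.05, strict `>`).
#' @return A tibble with one row per bin: the per-rule pass flags
#'   (`ok_ambiguous`, `ok_monoexonic`, `ok_count`, `ok_gene_density`,
#'   `ok_si`) and the overall `retained` flag.
#' @export
filter_bins <- function(counts, contrast = NULL, min_count = 5,
                        min_gene_density = 0.05, min_si = 0.05) {
  stopifnot(inherits(counts, "splice_counts"))
  bins <- counts$bins
  design <- counts$design
  genotypes <- unique(design$genotype)
  contrast <- contrast %||% genotypes

  bmat <- counts$bin_counts
  idx <- match(rownames(bmat), bins$bin_id)
  binfo <- bins[idx, , drop = FALSE]

  cmeans <- count_by_genotype(bmat, design)
  gdens <- density_by_genotype(counts, "gene")
  bdens <- density_by_genotype(counts, "bin")
  gd <- gdens[match(binfo$gene_id, rownames(gdens)), , drop = FALSE]
  si <- bdens / gd  # SI per genotype, rows aligned with bmat

  ok_amb <- !binfo$ambiguous
  ok_mono <- !binfo$monoexonic
  ok_count <- apply(cmeans >= min_count, 1L, all)
  ok_gd <- apply(gd > min_gene_density, 1L, function(z) all(z %in% TRUE))
  ok_si <- apply(si[, contrast, drop = FALSE] > min_si, 1L,
                 function(z) any(z %in% TRUE))

  tibble(
    bin_id = rownames(bmat), gene_id = binfo$gene_id, kind = binfo$kind,
    event_class = binfo$event_class,
    ok_ambiguous = ok_amb, ok_monoexonic = ok_mono, ok_count = ok_count,
    ok_gene_density = ok_gd, ok_si = ok_si,
    retained = ok_amb & ok_mono & ok_count & ok_gd & ok_si
  )
}

#' Bin-level differential splicing
#'
#' For the bins retained by [filter_bins()], runs the negative-binomial
#' conditional exact test on bin counts between the contrast genotypes,
#' computes the log2 fold change of bin read densities and the log2
#' Splicing Index Ratio from per-genotype mean densities, and adjusts
#' p-values by Benjamini-Hochberg separately within the AS-bin family
#' (annotated alternative splicing events) and the intron-bin family
#' (constitutive introns, i.e. candidate novel intron retention).  A bin
#' is called `altered` when all three strict thresholds hold:
#' |log2 FC| > `lfc_cutoff`, FDR < `fdr_cutoff` and
#' |log2 SIR| > `sir_cutoff`.
#'
#' @param counts A [splice_counts()] object.
#' @param contrast `c(reference_genotype, test_genotype)`.
#' @param lfc_cutoff,fdr_cutoff,sir_cutoff Call thresholds (defaults 0.58,
#'   0.15, 0.58).
#' @inheritParams filter_bins
#' @return An object of class `splicing_result`: a list with tibbles
#'   `as_events` and `intron_retention` (columns `bin_id`, `gene_id`,
#'   `event_class`, per-genotype densities and SIs, `log2_fc`, `log2_sir`,
#'   `p`, `fdr`, `altered`), the filter table `filters`, and the fitted
#'   dispersion.  `tidy()` binds the two tables; `glance()` summarizes.
#' @export
differential_splicing <- function(counts, contrast, lfc_cutoff = 0.58,
                                  fdr_cutoff = 0.15, sir_cutoff = 0.58,
                                  min_count = 5, min_gene_density = 0.05,
                                  min_si = 0.05) {
  stopifnot(inherits(counts, "splice_counts"))
  check_contrast(counts$design, contrast)
  ref <- contrast[1L]; tst <- contrast[2L]

  flt <- filter_bins(counts, contrast = contrast, min_count = min_count,
                     min_gene_density = min_gene_density, min_si = min_si)
  tested <- flt$bin_id[flt$retained & flt$kind %in% c("AS", "intron")]
  if (length(tested) == 0L) abort("no bins pass the splicing filters")

  sel <- counts$design$genotype %in% contrast
  sub_design <- counts$design[sel, , drop = FALSE]
  mat <- counts$bin_counts[tested, sub_design$sample_id, drop = FALSE]
  libs <- counts$lib_sizes[sub_design$sample_id]
  groups <- factor(sub_design$genotype, levels = contrast)

  disp <- estimate_common_dispersion(mat, groups, libs)
  res <- nb_exact_test(mat, groups, disp$phi, libs)

  bdens <- density_by_genotype(counts, "bin", genotypes = contrast)[tested, , drop = FALSE]
  gdens <- density_by_genotype(counts, "gene", genotypes = contrast)
  binfo <- counts$bins[match(tested, counts$bins$bin_id), , drop = FALSE]
  gd <- gdens[match(binfo$gene_id, rownames(gdens)), , drop = FALSE]

  si_ref <- splicing_index(bdens[, ref], gd[, ref])
  si_tst <- splicing_index(bdens[, tst], gd[, tst])
  dens_lfc <- ifelse(bdens[, ref] > 0 & bdens[, tst] > 0,
                     log2(bdens[, tst] / bdens[, ref]), NA_real_)

  rec <- tibble(
    bin_id = tested, gene_id = binfo$gene_id, kind = binfo$kind,
    event_class = binfo$event_class,
    bin_density_ref = bdens[, ref], bin_density_test = bdens[, tst],
    gene_density_ref = gd[, ref], gene_density_test = gd[, tst],
    si_ref = si_ref, si_test = si_tst,
    log2_fc = dens_lfc,
    log2_sir = splicing_index_ratio(si_tst, si_ref),
    p = res$p
  ) |>
    group_by(.data$kind) |>
    mutate(fdr = bh_adjust(.data$p)) |>   # separate BH families per kind
    ungroup() |>
    mutate(altered = !is.na(.data$log2_fc) & !is.na(.data$log2_sir) &
             abs(.data$log2_fc) > lfc_cutoff &
             .data$fdr < fdr_cutoff &
             abs(.data$log2_sir) > sir_cutoff)

  structure(
    list(
      as_events = filter(rec, .data$kind == "AS") |> select(-"kind"),
      intron_retention = filter(rec, .data$kind == "intron") |> select(-"kind"),
      filters = flt,
      contrast = contrast,
      phi = disp$phi,
      thresholds = c(lfc = lfc_cutoff, fdr = fdr_cutoff, sir = sir_cutoff,
                     min_count = min_count,
                     min_gene_density = min_gene_density, min_si = min_si)
    ),
    class = "splicing_result"
  )
}

#' @export
print.splicing_result <- function(x, ...) {
  cat("<splicing_result> ", x$contrast[2L], " vs ", x$contrast[1L],
      " (phi = ", format(x$phi, digits = 3), ")\n", sep = "")
  cat("  AS events tested: ", nrow(x$as_events), ", altered: ",
      sum(x$as_events$altered), "\n", sep = "")
  cat("  intron bins tested: ", nrow(x$intron_retention), ", altered: ",
      sum(x$intron_retention$altered), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.splicing_result <- function(x, ...) {
  bind_rows(
    mutate(x$as_events, table = "as_events", .before = 1L),
    mutate(x$intron_retention, table = "intron_retention", .before = 1L)
  )
}

#' @export
glance.splicing_result <- function(x, ...) {
  tibble(
    reference = x$contrast[1L], test = x$contrast[2L], phi = x$phi,
    n_as_tested = nrow(x$as_events),
    n_as_altered = sum(x$as_events$altered),
    n_intron_tested = nrow(x$intron_retention),
    n_intron_altered = sum(x$intron_retention$altered)
  )
}

#' Tally altered bins by event class and direction
#'
#' @param result A `splicing_result`, or a tibble of splicing records with
#'   columns `event_class`, `log2_sir`, `altered`.
#' @return A tibble `event_class`, `direction` (`+`/`-` by sign of the
#'   log2 SIR), `n`, for altered records only; empty when nothing is
#'   altered.  Row order is fixed (by class then direction) so the table
#'   is invariant to record permutation.
#' @export
event_category_breakdown <- function(result) {
  rec <- if (inherits(result, "splicing_result")) tidy(result) else result
  rec |>
    filter(.data$altered) |>
    mutate(direction = if_else(.data$log2_sir >= 0, "+", "-")) |>
    count(.data$event_class, .data$direction, name = "n") |>
    arrange(.data$event_class, .data$direction)
}

#' Overlap of altered bins between two splicing results
#'
#' @param a,b `splicing_result` objects over the same bin universe.
#' @param table `"intron_retention"` or `"as_events"`.
#' @return The [overlap_sets()] summary over bin ids, split by the sign of
#'   the log2 SIR.
#' @export
splicing_overlap <- function(a, b, table = c("intron_retention", "as_events")) {
  table <- match.arg(table)
  pick <- function(x, sgn) {
    d <- x[[table]]
    d$bin_id[d$altered & sign(d$log2_sir) == sgn]
  }
  overlap_sets(pick(a, 1), pick(a, -1), pick(b, 1), pick(b, -1))
}
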