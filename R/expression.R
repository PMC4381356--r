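# Gene-level differential expression with expression filters and
# cross-genotype overlap bookkeeping.

#' Filter genes by mean expression per condition
#'
#' Keeps genes whose mean raw count reaches `min_mean` in every condition
#' (genotype) of the design.  This strict all-conditions reading keeps
#' low-information genes out of dispersion estimation and testing.
#'
#' @param counts A [splice_counts()] object, or a gene count matrix.
#' @param design Required when `counts` is a matrix.
#' @param min_mean Minimum mean raw count per condition (default 10).
#' @return A tibble: `gene_id`, per-genotype mean columns, `retained`.
#' @export
filter_expressed <- function(counts, design = NULL, min_mean = 10) {
  if (inherits(counts, "splice_counts")) {
    design <- counts$design
    mat <- counts$gene_counts
  } else {
    mat <- as.matrix(counts)
    if (is.null(design)) abort("design required when counts is a matrix")
  }
  check_design(design)
  means <- count_by_genotype(mat, design)
  out <- as_tibble(means, rownames = "gene_id")
  out$retained <- apply(means >= min_mean, 1L, all)
  out
}

#' Gene-level differential expression
#'
#' Runs the expression filter, estimates a common dispersion from the
#' contrast samples, applies the negative-binomial conditional exact test
#' per retained gene, adjusts p-values by Benjamini-Hochberg across tested
#' genes, and calls genes `up` / `down` / `unchanged` using strict
#' thresholds on the fold change and FDR (defaults: |log2 FC| > 0.58,
#' FDR < 0.10).
#'
#' @param counts A [splice_counts()] object.
#' @param contrast `c(reference_genotype, test_genotype)`; fold changes are
#'   test over reference.
#' @param min_mean Expression filter threshold (mean raw count per
#'   condition), default 10.
#' @param lfc_cutoff,fdr_cutoff Call thresholds (strict inequalities).
#' @param normalization `"total"` (effective library = total assigned
#'   reads, the default) or `"tmm"` (library sizes rescaled by
#'   [tmm_factors()], robust to composition bias when many genes change
#'   in one direction).
#' @return A tibble of class `de_result`: `gene_id`, `mean_ref`,
#'   `mean_test`, `log2_fc`, `p`, `fdr`, `call`.  Attributes carry the
#'   contrast, dispersion and thresholds; see [glance.de_result()].
#' @export
differential_expression <- function(counts, contrast, min_mean = 10,
                                    lfc_cutoff = 0.58, fdr_cutoff = 0.10,
                                    normalization = c("total", "tmm")) {
  stopifnot(inherits(counts, "splice_counts"))
  check_contrast(counts$design, contrast)
  normalization <- match.arg(normalization)

  flt <- filter_expressed(counts, min_mean = min_mean)
  keep <- flt$gene_id[flt$retained]
  if (length(keep) == 0L) abort("no genes pass the expression filter")

  sel <- counts$design$genotype %in% contrast
  sub_design <- counts$design[sel, , drop = FALSE]
  mat <- counts$gene_counts[keep, sub_design$sample_id, drop = FALSE]
  libs <- counts$lib_sizes[sub_design$sample_id]
  if (normalization == "tmm") libs <- libs * tmm_factors(mat, libs)
  groups <- factor(sub_design$genotype, levels = contrast)

  disp <- estimate_common_dispersion(mat, groups, libs)
  res <- nb_exact_test(mat, groups, disp$phi, libs)

  means <- count_by_genotype(mat, sub_design, genotypes = contrast)
  out <- res |>
    rename(gene_id = "feature_id") |>
    mutate(
      mean_ref = means[, 1L],
      mean_test = means[, 2L],
      fdr = bh_adjust(.data$p),
      call = case_when(
        .data$fdr < fdr_cutoff & .data$log2_fc > lfc_cutoff ~ "up",
        .data$fdr < fdr_cutoff & .data$log2_fc < -lfc_cutoff ~ "down",
        TRUE ~ "unchanged"
      )
    ) |>
    select("gene_id", "mean_ref", "mean_test", "log2_fc", "p", "fdr", "call")

  structure(out,
            class = c("de_result", class(out)),
            contrast = contrast, phi = disp$phi,
            thresholds = c(min_mean = min_mean, lfc = lfc_cutoff,
                           fdr = fdr_cutoff),
            n_discarded = sum(!flt$retained))
}

#' @export
tidy.de_result <- function(x, ...) as_tibble(x)

#' Summary of a differential expression result
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return One-row tibble: contrast, dispersion, genes tested/discarded,
#'   and up/down call counts.
#' @export
glance.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  tibble(
    reference = ct[1L], test = ct[2L], phi = attr(x, "phi"),
    n_tested = nrow(x), n_discarded = attr(x, "n_discarded"),
    n_up = sum(x$call == "up"), n_down = sum(x$call == "down")
  )
}

#' Overlap of differential call sets across two contrasts
#'
#' Counts genes (or bins) called in the same or the opposite direction in
#' two analyses: `common_up`, `common_down`, and `antagonistic`
#' (up in one and down in the other).
#'
#' @param up_a,down_a,up_b,down_b Character vectors of feature ids.
#' @return A one-row tibble with per-set totals and overlap counts.
#' @export
overlap_sets <- function(up_a, down_a, up_b, down_b) {
  tibble(
    n_up_a = length(unique(up_a)), n_down_a = length(unique(down_a)),
    n_up_b = length(unique(up_b)), n_down_b = length(unique(down_b)),
    common_up = length(intersect(up_a, up_b)),
    common_down = length(intersect(down_a, down_b)),
    antagonistic = length(intersect(up_a, down_b)) +
      length(intersect(down_a, up_b))
  )
}

#' Overlap of two differential expression results
#'
#' @param a,b `de_result` objects over the same gene universe.
#' @return The [overlap_sets()] summary.
#' @export
de_overlap <- function(a, b) {
  overlap_sets(a$gene_id[a$call == "up"], a$gene_id[a$call == "down"],
               b$gene_id[b$call == "up"], b$gene_id[b$call == "down"])
}
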