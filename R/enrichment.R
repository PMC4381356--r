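# Representation-factor enrichment and hypergeometric overlap statistics.

check_overlap_args <- function(k, n1, n2, N) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("set sizes n1 and n2 must be positive")
  if (any(n1 > N) || any(n2 > N)) abort("set sizes cannot exceed the universe size")
  if (any(k < 0) || any(k > pmin(n1, n2))) {
    abort("overlap k must satisfy 0 <= k <= min(n1, n2)")
  }
  invisible(NULL)
}

#' Representation factor of a set overlap
#'
#' The representation factor is the observed overlap divided by the
#' overlap expected for two sets drawn independently from the universe:
#' `rf = k * N / (n1 * n2)`.  Values above 1 indicate more overlap than
#' expected by chance, below 1 less.
#'
#' @param k Observed overlap size.
#' @param n1,n2 Sizes of the two sets.
#' @param N Universe size.
#' @return The representation factor (vectorized).
#' @examples
#' representation_factor(20, 100, 50, 1000)  # expected 5, rf = 4
#' @export
representation_factor <- function(k, n1, n2, N) {
  check_overlap_args(k, n1, n2, N)
  k * N / (n1 * n2)
}

#' Hypergeometric tail probability of a set overlap
#'
#' With `X ~ Hypergeometric(N, n2, n1)` (the overlap of a random size-`n1`
#' set with a fixed size-`n2` set in a universe of `N`), returns
#' `P(X >= k)` for over-representation or `P(X <= k)` for
#' under-representation.
#'
#' @inheritParams representation_factor
#' @param direction `"over"` or `"under"`.
#' @return The tail probability (vectorized over `k`, `n1`, `n2`, `N`).
#' @export
overlap_pvalue <- function(k, n1, n2, N, direction = c("over", "under")) {
  direction <- match.arg(direction)
  check_overlap_args(k, n1, n2, N)
  if (direction == "over") {
    phyper(k - 1, n2, N - n2, n1, lower.tail = FALSE)
  } else {
    phyper(k, n2, N - n2, n1, lower.tail = TRUE)
  }
}

#' Representation-factor enrichment of a gene list
#'
#' Tests a gene list against each user-supplied functional category,
#' reporting the overlap, the expected overlap, the representation factor
#' and both hypergeometric tail probabilities.  Category memberships are
#' intersected with the universe first.  No multiple-testing correction is
#' applied across categories by default (raw p-values are reported and
#' flagged at `p_cutoff`); set `adjust = TRUE` for a Benjamini-Hochberg
#' adjusted flag instead.
#'
#' @param gene_list Character vector of gene ids (subset of `universe`).
#' @param categories Named list of character vectors, or a two-column data
#'   frame (`category_id`, `gene_id`).
#' @param universe Character vector of all eligible gene ids, e.g. the
#'   genes surviving the expression filter.
#' @param p_cutoff Significance flag threshold (default 0.05).
#' @param adjust If `TRUE`, flag on BH-adjusted p-values.
#' @return A tibble of class `enrichment_result`: `category_id`, `N`,
#'   `n1`, `n2`, `k`, `expected`, `rf`, `p_over`, `p_under`, `direction`,
#'   `significant`.
#' @export
enrich_list <- function(gene_list, categories, universe, p_cutoff = 0.05,
                        adjust = FALSE) {
  if (length(universe) == 0L) abort("empty universe")
  universe <- unique(universe)
  gene_list <- intersect(unique(gene_list), universe)
  if (is.data.frame(categories)) {
    categories <- split(categories[[2L]], categories[[1L]])
  }
  if (is.null(names(categories))) abort("categories must be named")

  out <- imap(categories, function(members, id) {
    cat_genes <- intersect(unique(members), universe)
    k <- length(intersect(gene_list, cat_genes))
    n1 <- length(gene_list)
    n2 <- length(cat_genes)
    N <- length(universe)
    if (n1 == 0L || n2 == 0L) {
      return(tibble(category_id = id, N = N, n1 = n1, n2 = n2, k = k,
                    expected = 0, rf = NA_real_, p_over = NA_real_,
                    p_under = NA_real_, direction = NA_character_))
    }
    expected <- n1 * n2 / N
    tibble(
      category_id = id, N = N, n1 = n1, n2 = n2, k = k, expected = expected,
      rf = representation_factor(k, n1, n2, N),
      p_over = overlap_pvalue(k, n1, n2, N, "over"),
      p_under = overlap_pvalue(k, n1, n2, N, "under"),
      direction = if (k >= expected) "over" else "under"
    )
  }) |>
    list_rbind()

  pmin_tail <- if_else(out$direction == "over", out$p_over, out$p_under)
  flag_p <- if (adjust) bh_adjust(replace(pmin_tail, is.na(pmin_tail), 1)) else pmin_tail
  out$significant <- !is.na(flag_p) & flag_p <= p_cutoff
  structure(out, class = c("enrichment_result", class(out)),
            p_cutoff = p_cutoff, adjusted = adjust)
}

#' @export
tidy.enrichment_result <- function(x, ...) as_tibble(x)

#' Read a category membership file
#'
#' Accepts a two-column TSV (`category_id`, `gene_id`) or a GMT file
#' (category, description, members...).
#'
#' @param path File path; format chosen by extension (`.gmt` vs TSV).
#' @return Named list of character vectors.
#' @export
read_categories <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t"), function(f) f[-c(1L, 2L)])
    names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
    sets
  } else {
    d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
    split(d[[2L]], d[[1L]])
  }
}
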