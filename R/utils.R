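# Internal helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}

# row means over a subset of columns, kept as a plain numeric vector
row_group_means <- function(mat, cols) {
  if (length(cols) == 1L) return(mat[, cols])
  rowMeans(mat[, cols, drop = FALSE])
}

# columns (sample ids) of a design belonging to one genotype
samples_of <- function(design, genotype) {
  design$sample_id[design$genotype == genotype]
}

check_design <- function(design) {
  need <- c("sample_id", "genotype", "replicate")
  if (!all(need %in% names(design))) {
    abort(paste0("design must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) abort("duplicate sample_id in design")
  tab <- table(design$genotype)
  if (any(tab == 0L)) abort("design contains a genotype with zero replicates")
  invisible(design)
}

check_contrast <- function(design, contrast) {
  if (length(contrast) != 2L) abort("contrast must name two genotypes: c(reference, test)")
  missing <- setdiff(contrast, unique(design$genotype))
  if (length(missing) > 0L) {
    abort(paste0("genotype(s) not present in design: ", paste(missing, collapse = ", ")))
  }
  invisible(contrast)
}
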