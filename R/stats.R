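# Statistical core: common-dispersion estimation, the negative-binomial
# conditional exact test, and FDR adjustment.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment returning values in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (FDR), same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# scale counts to the geometric-mean library size ("pseudo-counts")
equalize_libs <- function(mat, lib_sizes) {
  if (any(lib_sizes <= 0)) abort("library sizes must be positive")
  common <- geomean(lib_sizes)
  sweep(mat, 2L, common / lib_sizes, `*`)
}

# quantile-adjust counts to the geometric-mean library size: each count is
# mapped through its mid-quantile under NB(lambda * lib_s, phi) to the
# matching quantile under NB(lambda * L_common, phi), so equalized counts
# keep a negative-binomial distribution with the same dispersion.  With
# equal library sizes the mapping is the identity.
quantile_equalize <- function(mat, lib_sizes, phi) {
  if (any(lib_sizes <= 0)) abort("library sizes must be positive")
  common <- geomean(lib_sizes)
  if (all(abs(lib_sizes - common) < 1e-8 * common)) return(mat)
  lam <- rowSums(mat) / sum(lib_sizes)
  out <- mat
  for (s in seq_along(lib_sizes)) {
    mu_in <- lam * lib_sizes[s]
    mu_out <- lam * common
    y <- mat[, s]
    if (phi > 0) {
      pm <- pnbinom(y - 1, mu = mu_in, size = 1 / phi) +
        0.5 * dnbinom(y, mu = mu_in, size = 1 / phi)
      pm <- pmin(pmax(pm, 1e-10), 1 - 1e-10)
      out[, s] <- qnbinom(pm, mu = mu_out, size = 1 / phi)
    } else {
      pm <- ppois(y - 1, mu_in) + 0.5 * dpois(y, mu_in)
      pm <- pmin(pmax(pm, 1e-10), 1 - 1e-10)
      out[, s] <- qpois(pm, mu_out)
    }
  }
  out
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes TMM scaling factors relative to a reference sample: per-gene
#' log ratios (M) are weighted by inverse asymptotic variances, doubly
#' trimmed (30% on M, 5% on absolute expression A), and averaged.  Total
#' library sizes multiplied by these factors give effective library sizes
#' robust to composition bias from asymmetric differential expression.
#' Factors are normalized to have geometric mean 1.
#'
#' @param counts Integer matrix, features x samples.
#' @param lib_sizes Per-sample totals; defaults to column sums.
#' @return Numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  cpm75 <- apply(sweep(counts, 2L, lib_sizes, `/`), 2L, quantile, 0.75)
  ref <- which.min(abs(cpm75 - mean(cpm75)))
  yr <- counts[, ref]; Lr <- lib_sizes[ref]
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    ys <- counts[, s]; Ls <- lib_sizes[s]
    keep <- ys > 0 & yr > 0
    if (sum(keep) < 10L) return(1)
    ys <- ys[keep]; yr2 <- yr[keep]
    M <- log2((ys / Ls) / (yr2 / Lr))
    A <- 0.5 * log2((ys / Ls) * (yr2 / Lr))
    w <- (Ls - ys) / (Ls * ys) + (Lr - yr2) / (Lr * yr2)
    loM <- quantile(M, 0.30); hiM <- quantile(M, 0.70)
    loA <- quantile(A, 0.05); hiA <- quantile(A, 0.95)
    use <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(use)) return(1)
    2^(sum(M[use] / w[use]) / sum(1 / w[use]))
  }, 0)
  f / geomean(f)
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximizes the conditional log-likelihood of the counts given the
#' per-group totals (after equalizing library sizes to their geometric
#' mean), summed over features and groups, over the dispersion
#' \eqn{\phi} in the parameterization \eqn{Var = \mu + \phi \mu^2}.  The
#' search is a coarse log-spaced grid refined by golden-section
#' optimization; Poisson data drive the estimate to the \eqn{\phi = 0}
#' boundary.
#'
#' @param counts Integer matrix, features x samples.
#' @param groups Factor or character vector of group labels per sample.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return An object of class `dispersion_fit` with elements `phi`,
#'   `n_features` (features informing the fit) and `method`.
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) abort("all-zero count matrix")
  groups <- as.factor(groups)
  y <- equalize_libs(counts, lib_sizes)
  used <- rowSums(y) > 0
  y <- y[used, , drop = FALSE]
  gcols <- split(seq_along(groups), groups)
  gcols <- gcols[lengths(gcols) >= 2L]  # singleton groups carry no signal
  if (length(gcols) == 0L) abort("need at least one group with >= 2 samples")

  clik <- function(phi) {
    r <- 1 / phi
    total <- 0
    for (cols in gcols) {
      ng <- length(cols)
      yg <- y[, cols, drop = FALSE]
      z <- rowSums(yg)
      total <- total + sum(lgamma(yg + r)) - nrow(yg) * ng * lgamma(r) +
        sum(lgamma(ng * r) - lgamma(z + ng * r))
    }
    total
  }

  grid <- 10^seq(-6, 1, length.out = 29L)
  ll <- vapply(grid, clik, 0)
  best <- which.max(ll)
  if (best == 1L) {
    phi <- 0
  } else {
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(length(grid), best + 1L)]
    opt <- optimize(function(lp) clik(10^lp), lower = log10(lo),
                    upper = log10(hi), maximum = TRUE, tol = 1e-6)
    phi <- 10^opt$maximum
    if (phi < 1.5e-6) phi <- 0
  }
  structure(
    list(phi = phi, n_features = nrow(y), method = "conditional-ML"),
    class = "dispersion_fit"
  )
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat("<dispersion_fit> phi =", format(x$phi, digits = 4),
      "from", x$n_features, "features (", x$method, ")\n")
  invisible(x)
}

#' @export
tidy.dispersion_fit <- function(x, ...) {
  tibble(term = "common_dispersion", estimate = x$phi,
         n_features = x$n_features, method = x$method)
}

# conditional exact test for one feature.
# sa, sb: rounded group sums on the equalized-library scale; na, nb: group
# sizes.  Under common dispersion phi and equal effective library sizes,
# the group sum of na NB(mu, phi) replicates is NB with size na/phi, and
# the distribution of sa given the total t is negative hypergeometric
# (binomial for phi = 0), free of mu.  Two-sided p sums the probabilities
# of all splits no more likely than the observed one.
exact_test_one <- function(sa, sb, na, nb, phi) {
  t <- sa + sb
  if (t == 0L) return(1)
  x <- 0:t
  if (phi <= 0) {
    lw <- dbinom(x, t, na / (na + nb), log = TRUE)
  } else {
    ra <- na / phi
    rb <- nb / phi
    lw <- lchoose(x + ra - 1, x) + lchoose(t - x + rb - 1, t - x)
    lw <- lw - logsumexp(lw)
  }
  keep <- lw <= lw[sa + 1L] + 1e-8
  min(1, exp(logsumexp(lw[keep]) - logsumexp(lw)))
}

#' Negative-binomial conditional exact test
#'
#' Two-group exact test for overdispersed counts.  Library sizes are
#' equalized to their geometric mean, counts are summed per group, and the
#' conditional probability of the observed split of the total between the
#' groups is computed under a common-dispersion negative binomial.  The
#' two-sided p-value sums all splits with probability less than or equal
#' to that of the observed one (capped at 1).  With `phi = 0` the
#' conditional distribution reduces exactly to
#' Binomial(total, n_A / (n_A + n_B)) for equal libraries.
#'
#' The log2 fold change compares library-normalized group mean counts
#' (second group over first); a 0.5 pseudo-count is added to both groups
#' when either mean is zero.
#'
#' @param counts Matrix (features x samples) or vector of counts.
#' @param groups Two-level factor/character vector per sample; the fold
#'   change is level 2 versus level 1.
#' @param phi Common dispersion (`Var = mu + phi mu^2`), e.g. from
#'   [estimate_common_dispersion()].
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return A tibble: `feature_id`, `log2_fc`, `p`.
#' @examples
#' m <- rbind(f1 = c(0, 10), f2 = c(3, 7))
#' nb_exact_test(m, c("A", "B"), phi = 0, lib_sizes = c(100, 100))
#' @export
nb_exact_test <- function(counts, groups, phi, lib_sizes = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list("feature", NULL))
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  stopifnot_scalar_number(phi, "phi", min = 0)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) abort("groups must have exactly two levels")
  lib_sizes <- lib_sizes %||% colSums(counts)
  if (any(lib_sizes <= 0)) abort("library sizes must be positive")

  a_cols <- which(groups == levels(groups)[1L])
  b_cols <- which(groups == levels(groups)[2L])
  # quantile-adjusted pseudo-counts for the conditional enumeration;
  # proportionally scaled (CPM-style, exactly scale-invariant) sums for
  # the fold change
  q <- quantile_equalize(counts, lib_sizes, phi)
  qa <- rowSums(q[, a_cols, drop = FALSE])
  qb <- rowSums(q[, b_cols, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)), function(i) {
    exact_test_one(round(qa[i]), round(qb[i]),
                   length(a_cols), length(b_cols), phi)
  }, 0)

  y <- equalize_libs(counts, lib_sizes)
  sa <- rowSums(y[, a_cols, drop = FALSE])
  sb <- rowSums(y[, b_cols, drop = FALSE])

  mean_a <- sa / length(a_cols)
  mean_b <- sb / length(b_cols)
  zero <- mean_a == 0 | mean_b == 0
  mean_a[zero] <- mean_a[zero] + 0.5
  mean_b[zero] <- mean_b[zero] + 0.5
  lfc <- log2(mean_b / mean_a)
  lfc[round(sa) + round(sb) == 0] <- 0

  tibble(feature_id = rownames(counts) %||% as.character(seq_along(p)),
         log2_fc = lfc, p = p)
}
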