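# Gene-level differential expression: filters, calls and invariances.

sim_gene_counts <- function(n_null, n_de, lfc, phi, mu_range, seed,
                            n_reps = 3) {
  set.seed(seed)
  n <- n_null + n_de
  mu <- runif(n, mu_range[1], mu_range[2])
  mu_b <- mu * 2^c(rep(0, n_null), rep(lfc, n_de))
  draw <- function(m) {
    if (phi > 0) rnbinom(length(m), mu = m, size = 1 / phi) else rpois(length(m), m)
  }
  cols <- c(paste0("wt_", 1:n_reps), paste0("mut_", 1:n_reps))
  m <- cbind(
    matrix(draw(rep(mu, n_reps)), ncol = n_reps),
    matrix(draw(rep(mu_b, n_reps)), ncol = n_reps)
  )
  dimnames(m) <- list(sprintf("g%04d", 1:n), cols)
  bins <- tibble::tibble(
    bin_id = paste0(rownames(m), ":001"), gene_id = rownames(m),
    chrom = "chr1", start = 0L, end = 1000L, strand = "+", kind = "exon",
    event_class = "none", length = 1000L, ambiguous = FALSE,
    monoexonic = FALSE
  )
  bc <- m
  rownames(bc) <- bins$bin_id
  # the generative model gives every sample the same sequencing depth, so
  # the true library sizes are equal
  make_counts(bc, bins, genotypes = c("wt", "mut"), n_reps = n_reps,
              lib_sizes = setNames(rep(round(mean(colSums(m))), ncol(m)),
                                   colnames(m)))
}

test_that("the expression filter requires the mean in every condition", {
  m <- rbind(g1 = c(12, 12, 12, 11, 11, 11, 15, 15, 15),
             g2 = c(12, 12, 12, 4, 4, 4, 15, 15, 15))
  design <- tibble::tibble(
    sample_id = paste0("s", 1:9),
    genotype = rep(c("wt", "m1", "m2"), each = 3),
    replicate = rep(1:3, 3))
  colnames(m) <- design$sample_id
  flt <- filter_expressed(m, design, min_mean = 10)
  expect_true(flt$retained[flt$gene_id == "g1"])
  expect_false(flt$retained[flt$gene_id == "g2"])
  flt0 <- filter_expressed(m, design, min_mean = 0)
  expect_true(all(flt0$retained))
})

test_that("injected DE genes are recovered with few false calls", {
  sc <- sim_gene_counts(n_null = 200, n_de = 20, lfc = 2, phi = 0.1,
                        mu_range = c(30, 300), seed = 201)
  de <- differential_expression(sc, c("wt", "mut"))
  truth_de <- sprintf("g%04d", 201:220)
  called <- de$gene_id[de$call != "unchanged"]
  expect_gte(sum(truth_de %in% called), 16)
  expect_lte(sum(!called %in% truth_de), 3)
  expect_true(all(de$call[de$fdr >= 0.10] == "unchanged"))
  expect_true(all(abs(de$log2_fc[de$call != "unchanged"]) > 0.58))
})

test_that("TMM normalization absorbs composition bias from one-sided DE", {
  # realized totals as library sizes: the 4-fold DE genes inflate the
  # mutant libraries, shifting every null gene under total-count
  # normalization; TMM factors recover calibrated calls
  sc <- sim_gene_counts(n_null = 200, n_de = 20, lfc = 2, phi = 0.1,
                        mu_range = c(30, 300), seed = 205)
  sc$lib_sizes <- colSums(sc$gene_counts)
  truth_de <- sprintf("g%04d", 201:220)
  de_tc <- differential_expression(sc, c("wt", "mut"))
  de_tmm <- differential_expression(sc, c("wt", "mut"), normalization = "tmm")
  fp <- function(d) sum(!d$gene_id[d$call != "unchanged"] %in% truth_de)
  expect_lte(fp(de_tmm), 3)
  expect_lte(fp(de_tmm), fp(de_tc))
  expect_gte(sum(truth_de %in% de_tmm$gene_id[de_tmm$call != "unchanged"]), 16)
})

test_that("identical counts in both genotypes are unchanged with p = 1", {
  bins <- tibble::tibble(
    bin_id = "g1:001", gene_id = "g1", chrom = "chr1", start = 0L,
    end = 500L, strand = "+", kind = "exon", event_class = "none",
    length = 500L, ambiguous = FALSE, monoexonic = FALSE)
  bc <- matrix(50L, nrow = 1, ncol = 6,
               dimnames = list("g1:001", paste0("s", 1:6)))
  sc <- make_counts(bc, bins, genotypes = c("wt", "mut"), n_reps = 3)
  de <- differential_expression(sc, c("wt", "mut"), min_mean = 10)
  expect_equal(de$p, 1)
  expect_identical(de$call, "unchanged")
})

test_that("call thresholds are strict inequalities", {
  sc <- sim_gene_counts(n_null = 50, n_de = 5, lfc = 3, phi = 0.05,
                        mu_range = c(50, 100), seed = 202)
  de <- differential_expression(sc, c("wt", "mut"))
  top <- de[which.max(abs(de$log2_fc)), ]
  # re-run with the cutoff placed exactly at this gene's |log2_fc|
  de2 <- differential_expression(sc, c("wt", "mut"),
                                 lfc_cutoff = abs(top$log2_fc))
  expect_identical(de2$call[de2$gene_id == top$gene_id], "unchanged")
})

test_that("calls are invariant to replicate order within genotypes", {
  sc <- sim_gene_counts(n_null = 80, n_de = 8, lfc = 2, phi = 0.1,
                        mu_range = c(30, 200), seed = 203)
  de1 <- differential_expression(sc, c("wt", "mut"))
  perm <- c(3, 1, 2, 5, 6, 4)  # permute replicates within each genotype
  sc2 <- sc
  sc2$bin_counts <- sc$bin_counts[, perm]
  sc2$gene_counts <- sc$gene_counts[, perm]
  sc2$lib_sizes <- sc$lib_sizes[perm]
  sc2$design <- sc$design[perm, ]
  de2 <- differential_expression(sc2, c("wt", "mut"))
  expect_identical(de1$call, de2$call[match(de1$gene_id, de2$gene_id)])
})

test_that("set overlaps count common and antagonistic calls", {
  expect_equal(
    overlap_sets(c("g1", "g2"), character(0), c("g2", "g3"), character(0)) |>
      dplyr::select(common_up, antagonistic) |> unlist() |> unname(),
    c(1L, 0L))
  expect_equal(overlap_sets("g1", character(0), character(0), "g1")$antagonistic, 1L)
  expect_equal(
    overlap_sets("a", "b", "c", "d") |>
      dplyr::select(common_up, common_down, antagonistic) |> sum(),
    0L)
})

test_that("an unknown contrast genotype is an error", {
  sc <- sim_gene_counts(20, 0, 0, 0.1, c(30, 100), seed = 204)
  expect_error(differential_expression(sc, c("wt", "nope")), "not present")
})
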