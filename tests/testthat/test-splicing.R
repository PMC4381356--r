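# Splicing Index, Splicing Index Ratio, the filter cascade and calls.

test_that("splicing index arithmetic and degenerate cases", {
  expect_equal(splicing_index(0.02, 0.2), 0.1)
  expect_equal(splicing_index(0.3, 0.3), 1)
  expect_true(is.na(splicing_index(0.1, 0)))
  expect_error(splicing_index(-0.1, 0.2), "non-negative")
})

test_that("splicing index ratio is a log2 ratio with NA for zero SIs", {
  expect_equal(splicing_index_ratio(0.2, 0.1), 1)
  expect_equal(splicing_index_ratio(0.15, 0.15), 0)
  expect_equal(splicing_index_ratio(0.05, 0.2), -2)
  expect_true(is.na(splicing_index_ratio(0, 0.1)))
  expect_true(is.na(splicing_index_ratio(NA, 0.1)))
})

# deterministic two-gene fixture: gene G has exon/intron/exon + an AS bin,
# gene M is monoexonic
fixture_counts <- function(mut_scale_bin = 1, mut_scale_gene = 1) {
  bins <- tibble::tibble(
    bin_id = c("G:001", "G:002", "G:003", "G:004", "M:001"),
    gene_id = c("G", "G", "G", "G", "M"),
    chrom = "chr1", start = c(0L, 200L, 300L, 500L, 2000L),
    end = c(200L, 300L, 500L, 700L, 2500L), strand = "+",
    kind = c("exon", "intron", "AS", "exon", "exon"),
    event_class = c("none", "none", "IR", "none", "none"),
    length = c(200L, 100L, 200L, 200L, 500L),
    ambiguous = FALSE, monoexonic = c(F, F, F, F, T))
  base <- c(100, 20, 40, 100, 80)
  wt <- matrix(rep(base, 3), ncol = 3,
               dimnames = list(bins$bin_id, paste0("wt_", 1:3)))
  mut <- wt * mut_scale_gene
  mut["G:002", ] <- base["G:002" == bins$bin_id] * mut_scale_bin * mut_scale_gene
  colnames(mut) <- paste0("mut_", 1:3)
  m <- cbind(wt, mut)
  storage.mode(m) <- "integer"
  make_counts(m, bins, genotypes = c("wt", "mut"), n_reps = 3)
}

test_that("the filter cascade drops each rule's offenders", {
  sc <- fixture_counts()
  flt <- filter_bins(sc, contrast = c("wt", "mut"))
  expect_false(flt$retained[flt$bin_id == "M:001"])   # monoexonic
  expect_false(flt$ok_monoexonic[flt$bin_id == "M:001"])
  expect_true(all(flt$retained[flt$bin_id %in% c("G:002", "G:003")]))

  # low-count rule: mean below 5 in one condition
  sc2 <- fixture_counts()
  sc2$bin_counts["G:002", 1:3] <- 3L
  flt2 <- filter_bins(sc2, contrast = c("wt", "mut"))
  expect_false(flt2$ok_count[flt2$bin_id == "G:002"])

  # SI rule: an intron bin with low density relative to a busy gene
  # (counts still pass the mean-count filter)
  sc3 <- fixture_counts()
  m <- sc3$bin_counts
  m["G:001", ] <- 400L; m["G:004", ] <- 400L; m["G:002", ] <- 6L
  sc3 <- make_counts(m, sc3$bins, genotypes = c("wt", "mut"), n_reps = 3)
  flt3 <- filter_bins(sc3, contrast = c("wt", "mut"))
  expect_true(flt3$ok_count[flt3$bin_id == "G:002"])
  expect_false(flt3$ok_si[flt3$bin_id == "G:002"])
})

test_that("ambiguous bins never enter the analysis", {
  sc <- fixture_counts()
  sc$bins$ambiguous[sc$bins$bin_id == "G:003"] <- TRUE
  flt <- filter_bins(sc, contrast = c("wt", "mut"))
  expect_false(flt$retained[flt$bin_id == "G:003"])
})

test_that("an expression-only change is never called altered", {
  # all bins of G scaled 4x in the mutant: SI unchanged, log2 FC large
  sc <- fixture_counts(mut_scale_gene = 4)
  res <- differential_splicing(sc, c("wt", "mut"))
  rec <- tidy(res)
  g_rec <- rec[rec$gene_id == "G", ]
  expect_true(all(abs(g_rec$log2_sir) < 1e-9))
  expect_true(all(abs(g_rec$log2_fc - 2) < 1e-9))
  expect_false(any(g_rec$altered))
})

test_that("a bin-specific change passes all three thresholds", {
  sc <- fixture_counts(mut_scale_bin = 4)
  res <- differential_splicing(sc, c("wt", "mut"))
  ir <- res$intron_retention
  expect_equal(nrow(ir), 1L)
  expect_gt(ir$log2_sir, 0.58)
  expect_gt(abs(ir$log2_fc), 0.58)
  expect_true(ir$altered)
})

test_that("the SIR guard blocks large fold changes with flat SI", {
  rec <- tibble::tibble(
    bin_id = c("a", "b"), gene_id = "g", event_class = "IR",
    log2_fc = c(1, 1), log2_sir = c(1, 0.3), fdr = c(0.01, 0.01),
    altered = c(TRUE, FALSE))
  # contract encoded in differential_splicing: assert on the fixture above
  sc <- fixture_counts(mut_scale_gene = 3)   # fc ~ 1.58, sir ~ 0
  res <- differential_splicing(sc, c("wt", "mut"))
  expect_false(any(tidy(res)$altered))
})

test_that("SI is scale-free in counts and library sizes", {
  sc <- fixture_counts(mut_scale_bin = 2)
  r1 <- differential_splicing(sc, c("wt", "mut"))
  sc10 <- sc
  sc10$bin_counts <- sc$bin_counts * 10L
  sc10$gene_counts <- sc$gene_counts * 10L
  sc10$lib_sizes <- sc$lib_sizes * 10
  r2 <- differential_splicing(sc10, c("wt", "mut"))
  expect_equal(tidy(r1)$si_ref, tidy(r2)$si_ref, tolerance = 1e-9)
  expect_equal(tidy(r1)$log2_sir, tidy(r2)$log2_sir, tolerance = 1e-9)
})

test_that("AS-bins and intron-bins form separate BH families", {
  sc <- fixture_counts(mut_scale_bin = 4)
  res <- differential_splicing(sc, c("wt", "mut"))
  # each family's FDR equals a BH run on its own p-values
  expect_equal(res$intron_retention$fdr,
               bh_adjust(res$intron_retention$p))
  expect_equal(res$as_events$fdr, bh_adjust(res$as_events$p))
})

test_that("injected intron-retention events are recovered on synthetic data", {
  recalls <- c(); efdrs <- c()
  for (seed in c(301, 302)) {
    cfg <- sim_config(n_genes = 120, n_ir_events = 12, seed = seed)
    sim <- simulate_annotation(cfg)
    bins <- partition_bins(sim$exons)
    out <- simulate_counts(bins, cfg)
    res <- differential_splicing(out$counts, c("wt", "mut"))
    ir <- res$intron_retention
    inj <- out$truth$bin_id[out$truth$injected]
    called <- ir$bin_id[ir$altered]
    recalls <- c(recalls, sum(called %in% inj) / length(inj))
    efdrs <- c(efdrs, if (length(called)) sum(!called %in% inj) / length(called) else 0)
  }
  expect_gte(mean(recalls), 0.7)
  expect_lte(mean(efdrs), 0.2)
})

test_that("the event breakdown tallies altered bins by class and sign", {
  rec <- tibble::tibble(
    bin_id = letters[1:4], gene_id = "g",
    event_class = c("ES", "ES", "IR", "alt5"),
    log2_sir = c(1.2, 0.9, -1.5, 0.7),
    altered = c(TRUE, TRUE, TRUE, FALSE))
  tab <- event_category_breakdown(rec)
  expect_equal(tab$n[tab$event_class == "ES" & tab$direction == "+"], 2L)
  expect_equal(tab$n[tab$event_class == "IR" & tab$direction == "-"], 1L)
  expect_equal(nrow(tab), 2L)
  # permutation invariance
  tab2 <- event_category_breakdown(rec[c(3, 1, 4, 2), ])
  expect_identical(tab, tab2)
  # empty input
  empty <- event_category_breakdown(rec[rec$altered == FALSE & FALSE, ])
  expect_equal(nrow(empty), 0L)
})
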