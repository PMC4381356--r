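# The synthetic-data generator: determinism, structural guarantees,
# count moments and effect realization.

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 15, seed = 7)
  s1 <- simulate_annotation(cfg)
  s2 <- simulate_annotation(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$exons, s2$exons)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(s1, d1); p2 <- write_simulation(s2, d2)
  expect_identical(unname(tools::md5sum(p1$fasta)), unname(tools::md5sum(p2$fasta)))
  expect_identical(unname(tools::md5sum(p1$gff3)), unname(tools::md5sum(p2$gff3)))
})

test_that("an all-IR structure mix yields an IR AS-bin in every event gene", {
  cfg <- sim_config(n_genes = 30, monoexonic_frac = 0,
                    structure_mix = c(none = 0, ES = 0, IR = 1, alt5 = 0,
                                      alt3 = 0), seed = 8)
  sim <- simulate_annotation(cfg)
  bins <- partition_bins(sim$exons)
  ir_genes <- unique(bins$gene_id[bins$event_class == "IR"])
  expect_setequal(ir_genes, unique(sim$exons$gene_id))
})

test_that("primary-isoform introns all carry GT...AG ends", {
  cfg <- sim_config(n_genes = 25, seed = 9)
  sim <- simulate_annotation(cfg)
  primary <- sim$exons[grepl("\\.1$", sim$exons$transcript_id), ]
  introns <- annotated_introns(primary)
  expect_gt(nrow(introns), 0)
  expect_equal(nrow(gtag_introns(introns, sim$genome)), nrow(introns))
})

test_that("written annotation and genome round-trip through the readers", {
  cfg <- sim_config(n_genes = 10, seed = 10)
  sim <- simulate_annotation(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  ex <- read_annotation(paths$gff3)
  cols <- c("gene_id", "transcript_id", "start", "end", "strand")
  expect_identical(
    dplyr::arrange(ex[cols], gene_id, transcript_id, start),
    dplyr::arrange(sim$exons[cols], gene_id, transcript_id, start))
  g <- Biostrings::readDNAStringSet(paths$fasta)
  expect_identical(as.character(g[[1]]), as.character(sim$genome[[1]]))
})

test_that("phi = 0 counts are Poisson-like in their variance", {
  cfg <- sim_config(n_genes = 60, phi = 0, n_ir_events = 0, seed = 11,
                    n_reps = 50, genotypes = "wt")
  sim <- simulate_annotation(cfg)
  bins <- partition_bins(sim$exons)
  out <- simulate_counts(bins, cfg)
  m <- out$counts$bin_counts
  keep <- rowMeans(m) >= 20
  ratio <- apply(m[keep, ], 1, var) / rowMeans(m[keep, ])
  expect_lt(abs(mean(ratio) - 1), 0.2)
})

test_that("injected events realize their target log2 SIR", {
  realized <- c()
  for (seed in 21:30) {
    cfg <- sim_config(n_genes = 60, n_ir_events = 8, seed = seed)
    sim <- simulate_annotation(cfg)
    bins <- partition_bins(sim$exons)
    out <- simulate_counts(bins, cfg)
    sc <- out$counts
    bdens <- binsplice:::density_by_genotype(sc, "bin")
    gdens <- binsplice:::density_by_genotype(sc, "gene")
    inj <- out$truth$bin_id[out$truth$injected]
    gid <- out$truth$gene_id[out$truth$injected]
    si <- bdens[inj, ] / gdens[gid, ]
    realized <- c(realized, log2(si[, "mut"] / si[, "wt"]))
  }
  expect_lt(abs(mean(realized) - 1.5), 0.2)
})

test_that("zero depth produces all-zero tables", {
  cfg <- sim_config(n_genes = 10, reads_per_bin = 0, n_ir_events = 0,
                    seed = 12)
  sim <- simulate_annotation(cfg)
  bins <- partition_bins(sim$exons)
  out <- simulate_counts(bins, cfg)
  expect_true(all(out$counts$bin_counts == 0))
  expect_true(all(out$counts$gene_counts == 0))
})

test_that("an unreachable SIR target is an error naming the bin", {
  cfg <- sim_config(n_genes = 15, n_ir_events = 5, ir_log2_sir = 12,
                    seed = 13)
  sim <- simulate_annotation(cfg)
  bins <- partition_bins(sim$exons)
  expect_error(simulate_counts(bins, cfg), "unreachable")
})

test_that("counting a simulated BAM reproduces the ground-truth tallies", {
  cfg <- sim_config(n_genes = 10, seed = 14)
  sim <- simulate_annotation(cfg)
  bins <- partition_bins(sim$exons)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(sim, bins, n_reads = 2000,
                       out_bam = file.path(dir, "x.bam"))
  design <- tibble::tibble(sample_id = "x", bam_path = rd$bam,
                           genotype = "wt", replicate = 1L)
  sc <- count_reads(bins, design)
  truth <- setNames(rd$truth$count, rd$truth$bin_id)
  expect_identical(unname(sc$bin_counts[, "x"]),
                   unname(truth[rownames(sc$bin_counts)]))
})

test_that("junction reads leave spanned intron bins at zero", {
  # one two-exon gene, reads long enough that many span the junction
  cfg <- sim_config(n_genes = 4, monoexonic_frac = 0,
                    structure_mix = c(none = 1, ES = 0, IR = 0, alt5 = 0,
                                      alt3 = 0),
                    n_exons_range = c(2L, 2L), seed = 15)
  sim <- simulate_annotation(cfg)
  bins <- partition_bins(sim$exons)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(sim, bins, n_reads = 500,
                       out_bam = file.path(dir, "j.bam"))
  design <- tibble::tibble(sample_id = "j", bam_path = rd$bam,
                           genotype = "wt", replicate = 1L)
  sc <- count_reads(bins, design)
  intron_ids <- bins$bin_id[bins$kind == "intron" & !bins$ambiguous]
  expect_true(all(sc$bin_counts[intron_ids, "j"] == 0L))
  # and that some reads did span junctions (both flanking exons counted)
  expect_gt(sum(sc$bin_counts[, "j"]), rd$n_reads)
})

test_that("read simulation is deterministic in BAM content", {
  cfg <- sim_config(n_genes = 6, seed = 16)
  sim <- simulate_annotation(cfg)
  bins <- partition_bins(sim$exons)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_reads(sim, bins, 300, file.path(d1, "a.bam"))
  r2 <- simulate_reads(sim, bins, 300, file.path(d2, "a.bam"))
  expect_identical(unname(tools::md5sum(r1$bam)), unname(tools::md5sum(r2$bam)))
})

test_that("config validation rejects bad structure mixes and missing seeds", {
  expect_error(sim_config(structure_mix = c(none = 0.5, IR = 0.2), seed = 1),
               "sum to 1")
  expect_error(sim_config(), "seed")
})
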