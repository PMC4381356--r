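two_tx_gene <- function(gid, chrom, strand, tx_list, offset = 0L) {
  purrr::imap(tx_list, function(iv, tid) {
    tibble::tibble(gene_id = gid, transcript_id = paste0(gid, ".", tid),
                   chrom = chrom, start = as.integer(iv[, 1] + offset),
                   end = as.integer(iv[, 2] + offset), strand = strand)
  }) |> dplyr::bind_rows()
}

test_that("the alternative-acceptor worked example flattens correctly", {
  ex <- two_tx_gene("A", "chr1", "+", list(
    a = rbind(c(0, 100), c(200, 300)),
    b = rbind(c(0, 100), c(150, 300))
  ))
  bins <- flatten_gene(ex)
  expect_identical(bins$start, c(0L, 100L, 150L, 200L))
  expect_identical(bins$end, c(100L, 150L, 200L, 300L))
  expect_identical(bins$kind, c("exon", "intron", "AS", "exon"))
  expect_identical(bins$event_class, c("none", "none", "alt3", "none"))
})

test_that("the exon-skipping worked example flattens correctly", {
  ex <- two_tx_gene("B", "chr1", "+", list(
    a = rbind(c(0, 100), c(200, 250), c(300, 400)),
    b = rbind(c(0, 100), c(300, 400))
  ))
  bins <- flatten_gene(ex)
  expect_identical(bins$start, c(0L, 100L, 200L, 250L, 300L))
  expect_identical(bins$kind, c("exon", "intron", "AS", "intron", "exon"))
  expect_identical(bins$event_class[3], "ES")
})

test_that("a single-isoform gene has no AS bins", {
  ex <- two_tx_gene("C", "chr1", "+", list(a = rbind(c(0, 100), c(200, 300))))
  bins <- flatten_gene(ex)
  expect_identical(bins$kind, c("exon", "intron", "exon"))
  expect_true(all(bins$event_class == "none"))
})

test_that("a retained intron is classified IR", {
  ex <- two_tx_gene("D", "chr1", "+", list(
    spliced = rbind(c(0, 100), c(200, 300)),
    retained = rbind(c(0, 300))
  ))
  bins <- flatten_gene(ex)
  ir <- bins[bins$start == 100, ]
  expect_identical(ir$kind, "AS")
  expect_identical(ir$event_class, "IR")
})

test_that("alt5/alt3 classification is strand-aware", {
  # same geometry as the alt3 example but on the minus strand -> alt5
  ex <- two_tx_gene("E", "chr1", "-", list(
    a = rbind(c(0, 100), c(200, 300)),
    b = rbind(c(0, 100), c(150, 300))
  ))
  bins <- flatten_gene(ex)
  expect_identical(bins$event_class[bins$kind == "AS"], "alt5")
})

test_that("conflicting intronic classes give the multiple class", {
  # bin [150,200): alt3-like against tx a, ES-like against tx c
  ex <- two_tx_gene("F", "chr1", "+", list(
    a = rbind(c(0, 100), c(200, 300)),
    b = rbind(c(0, 100), c(150, 300)),
    c = rbind(c(0, 100), c(250, 300))
  ))
  bins <- flatten_gene(ex)
  expect_true("multiple" %in% bins$event_class)
})

test_that("bin totals add up across genes and the census matches", {
  gff <- system.file("extdata", "toy_genes.gff3", package = "binsplice")
  bins <- partition_bins(read_annotation(gff))
  cs <- bin_census(bins)
  expect_equal(cs$n_bins, 9L)
  expect_equal(cs$n_exon, 4L)
  expect_equal(cs$n_intron, 3L)
  expect_equal(cs$n_as, 2L)
  expect_equal(cs$n_alt3, 1L)
  expect_equal(cs$n_es, 1L)
  # two independent single-isoform two-exon genes: pure additivity
  ex <- dplyr::bind_rows(
    two_tx_gene("X", "chr2", "+", list(a = rbind(c(0, 100), c(200, 300)))),
    two_tx_gene("Y", "chr2", "+", list(a = rbind(c(0, 50), c(100, 200))),
                offset = 1000L)
  )
  cs2 <- bin_census(partition_bins(ex))
  expect_equal(c(cs2$n_exon, cs2$n_intron, cs2$n_as), c(4L, 2L, 0L))
})

test_that("bins overlapping another gene are flagged ambiguous", {
  ex <- dplyr::bind_rows(
    two_tx_gene("P", "chr3", "+", list(a = rbind(c(0, 100), c(200, 300)))),
    two_tx_gene("Q", "chr3", "-", list(a = rbind(c(250, 400))))
  )
  bins <- partition_bins(ex)
  p_last <- bins[bins$gene_id == "P" & bins$start == 200, ]
  expect_true(p_last$ambiguous)
  expect_true(all(bins$ambiguous[bins$gene_id == "Q"]))
  expect_false(any(bins$ambiguous[bins$gene_id == "P" & bins$end <= 250]))
})

test_that("duplicate gene ids across chromosomes are rejected", {
  ex <- dplyr::bind_rows(
    two_tx_gene("Z", "chr1", "+", list(a = rbind(c(0, 100)))),
    two_tx_gene("Z", "chr2", "+", list(a = rbind(c(0, 100))))
  )
  expect_error(partition_bins(ex), "duplicate gene_id")
})

test_that("bins tile each gene span with boundaries on exon edges", {
  set.seed(401)
  for (i in 1:100) {
    ex <- random_gene_model(sprintf("R%03d", i))
    bins <- flatten_gene(ex)
    span <- c(min(ex$start), max(ex$end))
    expect_identical(bins$start[1], span[1])
    expect_identical(bins$end[nrow(bins)], span[2])
    expect_true(all(bins$start[-1] == bins$end[-nrow(bins)]))  # disjoint, tiling
    expect_equal(sum(bins$length), span[2] - span[1])
    internal <- bins$start[-1]
    expect_true(all(internal %in% c(ex$start, ex$end)))
  }
})

test_that("bin kinds agree with per-base brute-force classification", {
  set.seed(402)
  for (i in 1:150) {
    ex <- random_gene_model(sprintf("S%03d", i))
    bins <- flatten_gene(ex)
    base_kind <- oracle_base_kinds(ex)
    span0 <- min(ex$start)
    expanded <- rep(bins$kind, bins$length)
    expect_identical(expanded, unname(base_kind))
  }
})

test_that("partitioning is deterministic", {
  gff <- system.file("extdata", "toy_genes.gff3", package = "binsplice")
  b1 <- partition_bins(read_annotation(gff))
  b2 <- partition_bins(read_annotation(gff))
  expect_identical(b1, b2)
})
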