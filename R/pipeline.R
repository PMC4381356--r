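# End-to-end orchestration: annotation -> bins -> counts -> DE ->
# splicing -> overlaps -> enrichment -> splice sites, from one config.

#' Build a run configuration
#'
#' All thresholds default to the values used throughout the package's
#' analysis stages: expression filter mean 10 reads/condition, bin filter
#' mean 5, gene density and SI floors 0.05, |log2 FC| 0.58, expression
#' FDR 0.10, splicing FDR 0.15, splice-site selection 2-fold at FDR 0.10,
#' enrichment p 0.05.
#'
#' @param annotation,genome,design Paths: GFF3/GTF, FASTA (optional,
#'   needed for splice-site analysis), and a design TSV with columns
#'   `sample_id`, `bam_path`, `genotype`, `replicate`.
#' @param contrasts List of `c(reference, test)` genotype pairs.
#' @param categories Optional path to a category TSV/GMT for enrichment.
#' @param out_dir Output directory.
#' @param thresholds Named list overriding any default threshold.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(annotation, design, contrasts, genome = NULL,
                       categories = NULL, out_dir = "binsplice_out",
                       thresholds = list(), seed = 1L) {
  defaults <- list(
    min_gene_mean = 10, min_bin_mean = 5, min_gene_density = 0.05,
    min_si = 0.05, lfc = 0.58, fdr_expression = 0.10, fdr_splicing = 0.15,
    site_fold = 2, site_fdr = 0.10, enrichment_p = 0.05,
    site_up = 3L, site_down = 10L
  )
  thresholds <- modifyList(defaults, thresholds)
  if (any(unlist(thresholds) <= 0)) abort("thresholds must be positive")
  structure(
    list(annotation = annotation, genome = genome, design = design,
         contrasts = contrasts, categories = categories, out_dir = out_dir,
         thresholds = thresholds, seed = seed),
    class = "run_config"
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file with keys matching the arguments of
#'   [run_config()] (`thresholds` as a nested map).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    annotation = y$annotation, design = y$design,
    contrasts = lapply(y$contrasts, unlist),
    genome = y$genome, categories = y$categories,
    out_dir = y$out_dir %||% "binsplice_out",
    thresholds = y$thresholds %||% list(),
    seed = y$seed %||% 1L
  )
}

#' Run the full analysis pipeline
#'
#' Executes partition, counting, differential expression, differential
#' splicing, cross-contrast overlaps, optional enrichment and optional
#' splice-site analysis, writing TSV results plus a JSON manifest
#' (package version, configuration, input checksums) under
#' `config$out_dir`.  Identical inputs and seed yield identical outputs.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  set.seed(config$seed)

  inform("stage: partition")
  exons <- read_annotation(config$annotation)
  bins <- partition_bins(exons)
  write_bins(bins, tsv = out("bins.tsv"), bed = out("bins.bed"))

  inform("stage: count")
  design <- readr::read_tsv(config$design, show_col_types = FALSE)
  counts <- count_reads(bins, design)
  readr::write_tsv(as_tibble(counts$bin_counts, rownames = "bin_id"),
                   out("bin_counts.tsv"))
  readr::write_tsv(as_tibble(counts$gene_counts, rownames = "gene_id"),
                   out("gene_counts.tsv"))
  readr::write_tsv(enframe(counts$lib_sizes, "sample_id", "library_size"),
                   out("library_sizes.tsv"))

  de <- list(); spl <- list()
  for (ct in config$contrasts) {
    tag <- paste0(ct[2L], "_vs_", ct[1L])
    inform(paste0("stage: differential expression (", tag, ")"))
    de[[tag]] <- differential_expression(
      counts, ct, min_mean = th$min_gene_mean,
      lfc_cutoff = th$lfc, fdr_cutoff = th$fdr_expression)
    readr::write_tsv(as_tibble(de[[tag]]), out(paste0("de_", tag, ".tsv")))

    inform(paste0("stage: differential splicing (", tag, ")"))
    spl[[tag]] <- differential_splicing(
      counts, ct, lfc_cutoff = th$lfc, fdr_cutoff = th$fdr_splicing,
      min_count = th$min_bin_mean, min_gene_density = th$min_gene_density,
      min_si = th$min_si)
    readr::write_tsv(spl[[tag]]$as_events, out(paste0("as_events_", tag, ".tsv")))
    readr::write_tsv(spl[[tag]]$intron_retention,
                     out(paste0("intron_retention_", tag, ".tsv")))
    readr::write_tsv(event_category_breakdown(spl[[tag]]),
                     out(paste0("event_breakdown_", tag, ".tsv")))
  }

  overlaps <- NULL
  if (length(de) >= 2L) {
    inform("stage: overlaps")
    overlaps <- bind_rows(
      mutate(de_overlap(de[[1L]], de[[2L]]), level = "gene", .before = 1L),
      mutate(splicing_overlap(spl[[1L]], spl[[2L]], "as_events"),
             level = "as_events", .before = 1L),
      mutate(splicing_overlap(spl[[1L]], spl[[2L]], "intron_retention"),
             level = "intron_retention", .before = 1L)
    )
    readr::write_tsv(overlaps, out("overlaps.tsv"))
  }

  enrich <- NULL
  if (!is.null(config$categories)) {
    inform("stage: enrichment")
    categories <- read_categories(config$categories)
    universe <- de[[1L]]$gene_id  # genes surviving the expression filter
    lists <- map(de, \(d) d$gene_id[d$call != "unchanged"])
    enrich <- imap(lists, \(gl, tag) {
      mutate(enrich_list(gl, categories, universe, p_cutoff = th$enrichment_p),
             contrast = tag, .before = 1L)
    }) |> list_rbind()
    readr::write_tsv(enrich, out("enrichment.tsv"))
  }

  sites <- NULL
  if (!is.null(config$genome)) {
    inform("stage: splice sites")
    genome <- load_genome(config$genome)
    introns <- annotated_introns(exons)
    background <- gtag_introns(introns, genome)
    bg_windows <- extract_windows(genome, background, "donor",
                                  up = th$site_up, down = th$site_down)
    sites <- imap(spl, function(s, tag) {
      sel <- select_top_events(s, fold = th$site_fold, fdr = th$site_fdr)
      if (nrow(sel) == 0L) return(NULL)
      ir <- counts$bins[match(sel$bin_id, counts$bins$bin_id), , drop = FALSE]
      fg_windows <- extract_windows(genome, ir, "donor",
                                    up = th$site_up, down = th$site_down)
      sm <- site_matrix(fg_windows, bg_windows)
      readr::write_tsv(as_tibble(sm), out(paste0("donor_sites_", tag, ".tsv")))
      sm
    })
  }

  manifest <- list(
    package = "binsplice",
    version = as.character(utils::packageVersion("binsplice")),
    seed = config$seed,
    thresholds = th,
    inputs = lapply(
      Filter(Negate(is.null),
             list(annotation = config$annotation, design = config$design,
                  genome = config$genome, categories = config$categories)),
      function(p) unname(tools::md5sum(p))
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  summary_lines <- c(
    paste0("binsplice run, seed ", config$seed),
    paste0("bins: ", nrow(bins), " (", sum(bins$kind == "AS"), " AS)"),
    vapply(names(de), function(tag) {
      g <- glance(de[[tag]]); s <- glance(spl[[tag]])
      sprintf("%s: %d up, %d down genes; %d AS events, %d IR bins altered",
              tag, g$n_up, g$n_down, s$n_as_altered, s$n_intron_altered)
    }, "")
  )
  writeLines(summary_lines, out("summary.txt"))

  invisible(list(bins = bins, counts = counts, de = de, splicing = spl,
                 overlaps = overlaps, enrichment = enrich, sites = sites,
                 manifest = manifest))
}
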