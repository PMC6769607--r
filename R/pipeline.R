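#' Run the full differential-methylation pipeline
#'
#' Orchestrates simulate/load -> bin -> test -> annotate -> enrich -> link
#' -> report as one deterministic run. Inputs come either from a simulated
#' study bundle (`config$simulate`, passed to [simulate_methylome_study()])
#' or from files (`config$inputs` with `genome`, `counts`, `genes`, `tads`,
#' `conservation`, optionally `gene_sets` and `mapping`). Identical
#' configuration and inputs produce byte-identical outputs.
#'
#' Configuration entries (all optional, defaults in parentheses):
#' `bin_width` (500), `mre_motifs` (CCGG/GCGC/CCGC), `alpha` (0.05),
#' `merge_adjacent` (FALSE), `promoter_flank`/`downstream_flank` (1500),
#' `shore_flank` (2000), `cons_threshold` (0.5), `tad_window` (1e6),
#' `min_count` (2), `min_fold` (1.5), `seed` (1), `out_dir`.
#'
#' Outputs written to `out_dir`: `dmrs.bed` (name = direction, score =
#' -log10 q), `dmr_annotation.tsv`, `summary.json`, `enrichment.tsv`,
#' `tad_links.tsv`, `islands.bed`, and `manifest.json` (configuration, its
#' MD5 hash, and the seed).
#'
#' @param config Named list (or path to a JSON file with one).
#' @return Invisibly, a list with every intermediate result: `counts`,
#'   `results`, `dmrs`, `summary`, `annotated`, `context_summary`,
#'   `islands`, `shores`, `dmg`, `enrichment`, `clusters`, `tad_links`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    bin_width = 500, mre_motifs = c("CCGG", "GCGC", "CCGC"),
    alpha = 0.05, merge_adjacent = FALSE,
    promoter_flank = 1500, downstream_flank = 1500, shore_flank = 2000,
    cons_threshold = 0.5, tad_window = 1e6,
    min_count = 2, min_fold = 1.5, exact_threshold = 20,
    seed = 1, out_dir = NULL), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # ---- load or simulate inputs
  inputs <- stage("inputs", {
    if (!is.null(cfg$study)) {
      cfg$study
    } else if (!is.null(cfg$simulate)) {
      do.call(simulate_methylome_study,
              utils::modifyList(list(seed = cfg$seed, bin_width = cfg$bin_width,
                                     mre_motifs = cfg$mre_motifs),
                                as.list(cfg$simulate)))
    } else if (!is.null(cfg$inputs)) {
      genome <- read_genome_fasta(cfg$inputs$genome)
      lens <- setNames(Biostrings::width(genome), names(genome))
      counts <- read_count_table(cfg$inputs$counts)
      list(genome = genome, counts = counts,
           truth = list(genes = read_gene_models(cfg$inputs$genes, lens),
                        tads = read_bed3(cfg$inputs$tads),
                        conservation = read_conservation(cfg$inputs$conservation,
                                                         lens)))
    } else stopf("config needs 'study', 'simulate' or 'inputs'")
  })
  genome <- inputs$genome
  counts <- inputs$counts
  genes <- inputs$truth$genes
  tads <- inputs$truth$tads
  conservation <- inputs$truth$conservation

  # ---- per-bin test and DMR calls
  results <- stage("mnm_test", mnm_test_all(counts,
                                            exact_threshold = cfg$exact_threshold))
  calls <- stage("call_dmrs", call_dmrs(results, alpha = cfg$alpha,
                                        merge_adjacent = cfg$merge_adjacent))

  # ---- annotation
  islands <- stage("islands", find_cpg_islands(genome))
  shores <- stage("shores", derive_shores(islands, flank = cfg$shore_flank,
                                          genome_lengths = setNames(
                                            Biostrings::width(genome), names(genome))))
  annotated <- stage("annotate", annotate_dmrs(calls$dmrs, islands, shores, genes,
                                               cfg$promoter_flank, cfg$downstream_flank))
  context_summary <- stage("summarize",
                           if (nrow(annotated)) summarize_contexts(annotated)
                           else suppressWarnings(summarize_contexts(annotated)))

  # ---- enrichment of gene-associated DMRs
  gene_sets <- if (!is.null(cfg$inputs$gene_sets)) read_gmt(cfg$inputs$gene_sets)
               else cfg$gene_sets
  dmg <- stage("dmg", dmr_genes(calls$dmrs, genes,
                                cfg$promoter_flank, cfg$downstream_flank))
  enrichment <- clusters <- NULL
  if (!is.null(gene_sets) && length(dmg)) {
    enrichment <- stage("enrich",
                        enrich_terms(dmg, gene_sets,
                                     background_genes = unique(genes$gene_id),
                                     min_count = cfg$min_count,
                                     min_fold = cfg$min_fold))
    clusters <- stage("cluster", cluster_terms(attr(enrichment, "all_terms") %||%
                                               enrichment))
  }

  # ---- intergenic DMRs: conservation filter + TAD linkage
  mapping <- if (!is.null(cfg$inputs$mapping)) read_mapping_table(cfg$inputs$mapping)
  intergenic <- annotated[annotated$gene_context == "intergenic", , drop = FALSE]
  tad_links <- stage("tad_linkage",
                     if (nrow(intergenic))
                       link_intergenic_dmrs(intergenic, conservation, tads, genes,
                                            mapping = mapping,
                                            cons_threshold = cfg$cons_threshold,
                                            window = cfg$tad_window)
                     else NULL)

  bundle <- list(counts = counts, results = results, dmrs = calls$dmrs,
                 summary = calls$summary, annotated = annotated,
                 context_summary = context_summary, islands = islands,
                 shores = shores, dmg = dmg, enrichment = enrichment,
                 clusters = clusters, tad_links = tad_links)

  # ---- outputs
  if (!is.null(cfg$out_dir)) {
    bundle$manifest <- stage("write", write_pipeline_outputs(bundle, cfg))
  }
  invisible(bundle)
}

write_pipeline_outputs <- function(bundle, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  dmrs <- bundle$dmrs
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = dmrs$direction,
                    score = round(-log10(pmax(dmrs$q_value, 1e-300)), 4),
                    strand = ".")
  write.table(bed, out("dmrs.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(bundle$annotated, out("dmr_annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed3(bundle$islands, out("islands.bed"))

  summary <- list(dmrs = bundle$summary,
                  contexts = list(
                    total = bundle$context_summary$total,
                    gene_context = bundle$context_summary$gene_context,
                    island_context = bundle$context_summary$island_context))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (!is.null(bundle$enrichment) && nrow(bundle$enrichment)) {
    enr <- bundle$enrichment
    enr$members <- vapply(enr$members, paste, character(1), collapse = ",")
    write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(bundle$tad_links)) {
    tl <- bundle$tad_links
    tl$contact_genes <- vapply(tl$contact_genes, paste, character(1),
                               collapse = ",")
    write.table(tl, out("tad_links.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  cfg_json <- out("config.json")
  # hash the scientific configuration only, not run-local paths
  keep <- cfg[setdiff(names(cfg), c("study", "gene_sets", "out_dir", "inputs"))]
  jsonlite::write_json(keep, cfg_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_json)),
                   seed = cfg$seed,
                   n_bins = nrow(bundle$counts),
                   n_dmrs = nrow(bundle$dmrs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}
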