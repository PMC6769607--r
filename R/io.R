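# File formats: FASTA for sequence, BED3 for plain intervals, bedGraph for
# conservation, GMT for gene sets, TSV for tables. All interval files are
# 0-based half-open.

#' Write and read the per-bin count table
#'
#' TSV with columns `chrom`, `start`, `end`, `cpg`, `mre_sites`,
#' `medip_<i>`, `mre_<i>`.
#'
#' @param counts Count table ([bin_count_table()]).
#' @param path File path.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` the `data.frame`.
#' @export
write_count_table <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "cpg", "mre_sites")
  if (!all(need %in% colnames(df)))
    stopf("count table %s lacks columns %s", path,
          paste(setdiff(need, colnames(df)), collapse = ", "))
  df
}

#' Write and read gene models
#'
#' TSV with `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#' `strand`; TSS/TES are implied by strand (TSS = start on `+`, end on
#' `-`).
#'
#' @param genes `GRanges` with `gene_id`.
#' @param path File path.
#' @param genome_lengths Optional named lengths attached as `seqlengths` on
#'   read.
#' @return `write_gene_models()` returns `path` invisibly;
#'   `read_gene_models()` a `GRanges`.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(gene_id = genes$gene_id,
                   chrom = as.character(seqnames(genes)),
                   start = start(genes) - 1L, end = end(genes),
                   strand = as.character(strand(genes)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path, genome_lengths = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand)
  gr$gene_id <- df$gene_id
  if (!is.null(genome_lengths))
    seqlengths(gr) <- genome_lengths[seqlevels(gr)]
  gr
}

#' Interval and track I/O wrappers
#'
#' Thin wrappers over `rtracklayer` (BED, bedGraph) and `Biostrings`
#' (FASTA) fixing the formats used throughout: `write_bed3()`/`read_bed3()`
#' for plain interval sets (TADs, DMRs, islands), `write_conservation()`/
#' `read_conservation()` for per-base scores, `write_genome_fasta()`/
#' `read_genome_fasta()` for sequence.
#'
#' @param gr `GRanges` to write.
#' @param path File path.
#' @param track Conservation `RleList`.
#' @param genome `DNAStringSet`.
#' @param genome_lengths Named lengths giving each chromosome's extent
#'   (required to materialise a dense score track on read).
#' @name interval_io
NULL

#' @rdname interval_io
#' @export
write_bed3 <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname interval_io
#' @export
read_bed3 <- function(path) {
  if (file.size(path) == 0) return(GRanges())
  gr <- rtracklayer::import(path, format = "BED")
  mcols(gr) <- NULL
  gr
}

#' @rdname interval_io
#' @export
write_conservation <- function(track, path) {
  grl <- lapply(names(track), function(chrom) {
    v <- track[[chrom]]
    GRanges(chrom, IRanges(start(v), end(v)), score = runValue(v))
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname interval_io
#' @export
read_conservation <- function(path, genome_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(names(genome_lengths), function(chrom) {
    v <- Rle(0, genome_lengths[[chrom]])
    sub <- gr[as.character(seqnames(gr)) == chrom]
    for (i in seq_along(sub))
      v[start(sub)[i]:end(sub)[i]] <- sub$score[i]
    v
  })
  as(setNames(out, names(genome_lengths)), "RleList")
}

#' @rdname interval_io
#' @export
write_genome_fasta <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname interval_io
#' @export
read_genome_fasta <- function(path) readDNAStringSet(path)

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes (tab-separated).
#' Backed by [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets in GMT format
#'
#' @param gene_sets Named list of character vectors.
#' @param path File path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the planted truth of a simulated study
#'
#' JSON record of the generation parameters and planted features of a
#' [simulate_methylome_study()] bundle: island/TAD coordinates (0-based
#' half-open), DMR bin indices and directions, library sizes — everything
#' needed to score a pipeline run against the truth without the R object.
#'
#' @param study Bundle from [simulate_methylome_study()].
#' @param path File path.
#' @export
write_truth_json <- function(study, path) {
  gr_df <- function(gr) if (length(gr))
    data.frame(chrom = as.character(seqnames(gr)),
               start = start(gr) - 1L, end = end(gr)) else list()
  truth <- list(params = study$params,
                islands = gr_df(study$truth$islands),
                tads = gr_df(study$truth$tads),
                conserved_blocks = gr_df(study$truth$conserved_blocks),
                dmr_bins = study$truth$dmr_bins,
                dmr_direction = study$truth$dmr_direction,
                library_sizes = study$truth$library_sizes)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a coordinate-mapping block table
#'
#' TSV with columns `src_chrom`, `src_start`, `src_end`, `tgt_chrom`,
#' `tgt_start` (0-based half-open), as consumed by [map_interval()].
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_mapping_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
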