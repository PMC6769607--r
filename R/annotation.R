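# island criteria on [s, e] (1-based, inclusive) given 0-padded indicator
# cumsums (sum over 1..p is v[p + 1]); O/E uses the Gardiner-Garden
# convention (N_CpG * L) / (N_C * N_G)
island_window_stats <- function(cums, s, e) {
  L <- e - s + 1
  nC <- cums$C[e + 1] - cums$C[s]
  nG <- cums$G[e + 1] - cums$G[s]
  # CG dinucleotides fully inside the window start at s .. e-1
  nCG <- cums$CG[pmax(e, s)] - cums$CG[s]
  gc <- (nC + nG) / L
  oe <- ifelse(nC * nG > 0, nCG * L / (nC * nG), 0)
  list(length = L, gc = gc, oe = oe)
}

island_criteria_ok <- function(st, min_len, min_gc, min_oe) {
  st$length >= min_len & st$gc > min_gc & st$oe > min_oe
}

seq_cumsums <- function(seq) {
  ch <- strsplit(as.character(seq), "", fixed = TRUE)[[1]]
  isC <- ch == "C"; isG <- ch == "G"
  isCG <- c(isC[-length(ch)] & isG[-1], FALSE)
  list(C = c(0, cumsum(isC)), G = c(0, cumsum(isG)), CG = c(0, cumsum(isCG)))
}

find_islands_one <- function(seq, min_len, min_gc, min_oe,
                             seed_width = 200L, merge_gap = 100L) {
  L <- length(seq)
  if (L < seed_width) return(IRanges())
  cums <- seq_cumsums(seq)
  starts <- seq_len(L - seed_width + 1L)
  st <- island_window_stats(cums, starts, starts + seed_width - 1L)
  seed <- st$gc > min_gc & st$oe > min_oe
  if (!any(seed)) return(IRanges())
  seeds <- IRanges(starts[seed], width = seed_width)
  merged <- reduce(seeds, min.gapwidth = merge_gap)    # gap < merge_gap merges
  keep <- IRanges()
  for (k in seq_along(merged)) {
    s <- start(merged)[k]; e <- end(merged)[k]
    repeat {
      stk <- island_window_stats(cums, s, e)
      if (island_criteria_ok(stk, min_len, min_gc, min_oe)) {
        keep <- c(keep, IRanges(s, e)); break
      }
      s <- s + 1L; e <- e - 1L
      if (e - s + 1 < min_len) break
    }
  }
  # hard postcondition: every emitted interval re-satisfies the criteria
  if (length(keep)) {
    stf <- island_window_stats(cums, start(keep), end(keep))
    stopifnot(all(island_criteria_ok(stf, min_len, min_gc, min_oe)))
  }
  keep
}

#' Detect CpG islands in genomic sequence
#'
#' A CpG island is a maximal segment satisfying (i) length greater than
#' 200 bp, (ii) GC content greater than 50%, and (iii) observed-to-expected
#' CpG ratio greater than 0.6, with O/E computed as
#' `(N_CpG x L) / (N_C x N_G)`. The search slides 200 bp seed windows at
#' 1 bp steps, keeps windows meeting the GC and O/E thresholds, merges
#' seed runs separated by less than 100 bp, and symmetrically trims each
#' merged segment until the whole segment meets all three criteria
#' (segments shrinking below the length threshold are dropped). Every
#' emitted island is re-verified against the criteria.
#'
#' @param genome Named `DNAStringSet`, single `DNAString`, or character
#'   scalar (then reported on chromosome `"seq"`).
#' @param min_len Minimum island length (default 201, i.e. strictly more
#'   than 200 bp).
#' @param min_gc,min_oe Strict lower bounds on GC content and O/E ratio.
#' @return `GRanges` of islands (empty when none found).
#' @export
find_cpg_islands <- function(genome, min_len = 201, min_gc = 0.5, min_oe = 0.6) {
  if (is.character(genome)) genome <- DNAStringSet(c(seq = genome))
  if (is(genome, "DNAString")) genome <- DNAStringSet(c(seq = as.character(genome)))
  out <- GRanges()
  for (chrom in names(genome)) {
    ir <- find_islands_one(genome[[chrom]], min_len, min_gc, min_oe)
    if (length(ir)) out <- c(out, GRanges(chrom, ir))
  }
  if (length(out)) {
    seqlengths(out) <- setNames(Biostrings::width(genome),
                                names(genome))[seqlevels(out)]
  }
  sort(out)
}

#' Derive CpG shores from islands
#'
#' Shores are the `flank`-bp regions immediately upstream and downstream of
#' each island, clipped at chromosome ends, with any overlap against an
#' island removed and overlapping shore fragments merged.
#'
#' @param islands `GRanges` of disjoint islands.
#' @param flank Shore width in bases (default 2000).
#' @param genome_lengths Named chromosome lengths (defaults to the islands'
#'   `seqlengths`).
#' @return `GRanges` of shores, disjoint from the islands.
#' @export
derive_shores <- function(islands, flank = 2000, genome_lengths = NULL) {
  if (!length(islands)) return(GRanges())
  if (!is.null(genome_lengths)) seqlengths(islands) <- genome_lengths[seqlevels(islands)]
  left <- suppressWarnings(flank(islands, flank, start = TRUE, ignore.strand = TRUE))
  right <- suppressWarnings(flank(islands, flank, start = FALSE, ignore.strand = TRUE))
  shores <- suppressWarnings(trim(reduce(c(left, right))))
  out <- setdiff(shores, islands, ignore.strand = TRUE)
  sort(reduce(out))
}

#' Classify DMRs by island and gene context
#'
#' Each region receives exactly one label per axis, by any-overlap with a
#' fixed precedence: island > shore > open sea for the island axis;
#' promoter > intragenic > downstream > intergenic for the gene axis.
#' Promoters are the `promoter_flank` bp upstream of the transcription start
#' site and downstream regions the `downstream_flank` bp past the
#' transcription end site, on the gene's own strand.
#'
#' @param dmrs `GRanges` (or the `dmrs` data.frame from [call_dmrs()]).
#' @param islands,shores `GRanges` from [find_cpg_islands()] /
#'   [derive_shores()].
#' @param genes `GRanges` of gene bodies with strand and a `gene_id` column.
#' @param promoter_flank,downstream_flank Flank widths in bases (default
#'   1500).
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open),
#'   `island_context` and `gene_context`.
#' @export
annotate_dmrs <- function(dmrs, islands, shores, genes,
                          promoter_flank = 1500, downstream_flank = 1500) {
  gr <- as_dmr_granges(dmrs)
  promoters <- trim(suppressWarnings(flank(genes, promoter_flank, start = TRUE)))
  downstream <- trim(suppressWarnings(flank(genes, downstream_flank, start = FALSE)))
  island_context <- ifelse(overlapsAny(gr, islands, ignore.strand = TRUE), "island",
                    ifelse(overlapsAny(gr, shores, ignore.strand = TRUE), "shore",
                           "open"))
  gene_context <- ifelse(overlapsAny(gr, promoters, ignore.strand = TRUE), "promoter",
                  ifelse(overlapsAny(gr, genes, ignore.strand = TRUE), "intragenic",
                  ifelse(overlapsAny(gr, downstream, ignore.strand = TRUE), "downstream",
                         "intergenic")))
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
             end = end(gr), island_context = island_context,
             gene_context = gene_context, stringsAsFactors = FALSE)
}

as_dmr_granges <- function(dmrs) {
  if (is(dmrs, "GRanges")) return(dmrs)
  GRanges(dmrs$chrom, IRanges(dmrs$start + 1L, dmrs$end))
}

#' Summarise DMR context categories
#'
#' Counts and percentages per gene-context and island-context category,
#' with percentages computed on the full DMR total and rounded half-up to
#' one decimal. Either pass an annotated DMR table, or pass per-category
#' counts directly (e.g. counts taken from a publication) together with the
#' DMR total to use as the percentage denominator.
#'
#' @param annotated Output of [annotate_dmrs()] (or `NULL` when counts are
#'   given directly).
#' @param gene_counts,island_counts Named integer vectors of per-category
#'   counts (names among `intergenic`/`intragenic`/`promoter`/`downstream`
#'   and `island`/`shore`/`open`), used when `annotated` is `NULL`.
#' @param total DMR total used as the percentage denominator; defaults to
#'   `nrow(annotated)`.
#' @return List with `total`, `gene_context` and `island_context`, each a
#'   `data.frame` of counts and percentages.
#' @examples
#' summarize_contexts(gene_counts = c(intergenic = 3, intragenic = 1),
#'                    island_counts = c(shore = 2, open = 2), total = 4)
#' @export
summarize_contexts <- function(annotated = NULL, gene_counts = NULL,
                               island_counts = NULL, total = NULL) {
  gene_levels <- c("intergenic", "intragenic", "promoter", "downstream")
  island_levels <- c("island", "shore", "open")
  if (!is.null(annotated)) {
    total <- total %||% nrow(annotated)
    gene_counts <- vapply(gene_levels, function(l)
      sum(annotated$gene_context == l), integer(1))
    island_counts <- vapply(island_levels, function(l)
      sum(annotated$island_context == l), integer(1))
  } else {
    if (is.null(total)) stopf("total is required when passing counts directly")
  }
  if (total == 0) warning("empty DMR set; percentages reported as 0")
  one_axis <- function(counts, levels) {
    n <- setNames(integer(length(levels)), levels)
    n[names(counts)] <- as.integer(counts)
    pct <- if (total > 0) round_half_up(100 * n / total) else rep(0, length(n))
    data.frame(category = levels, count = unname(n), percent = unname(pct),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(total = total,
       gene_context = one_axis(gene_counts, gene_levels),
       island_context = one_axis(island_counts, island_levels))
}

#' Genes associated with DMRs
#'
#' Differentially methylated genes (DMGs): genes whose body or 1500 bp
#' flanks overlap at least one DMR — i.e. genes responsible for any
#' promoter/intragenic/downstream context label.
#'
#' @inheritParams annotate_dmrs
#' @return Character vector of `gene_id`s.
#' @export
dmr_genes <- function(dmrs, genes, promoter_flank = 1500, downstream_flank = 1500) {
  gr <- as_dmr_granges(dmrs)
  ext <- punion(trim(suppressWarnings(flank(genes, promoter_flank, start = TRUE))),
                genes, fill.gap = TRUE, ignore.strand = TRUE)
  ext <- punion(ext, trim(suppressWarnings(flank(genes, downstream_flank, start = FALSE))),
                fill.gap = TRUE, ignore.strand = TRUE)
  hit <- overlapsAny(ext, gr, ignore.strand = TRUE)
  unique(genes$gene_id[hit])
}
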