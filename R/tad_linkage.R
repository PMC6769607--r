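#' Mean conservation over an interval
#'
#' Averages per-base conservation scores (in `[0, 1]`, e.g. phastCons) over
#' an interval; bases with no recorded score contribute 0. The filter is
#' strict: the interval passes only if the mean exceeds `threshold`.
#'
#' @param interval Single-range `GRanges` (or a data frame row with
#'   `chrom`/`start`/`end`, 0-based half-open).
#' @param track `RleList` of per-base scores per chromosome (e.g. from
#'   [read_conservation()]).
#' @param threshold Strict lower bound on the mean (default 0.5).
#' @return List with `mean_score` and logical `passes`.
#' @export
mean_conservation <- function(interval, track, threshold = 0.5) {
  gr <- as_dmr_granges(interval)
  stopifnot(length(gr) == 1L)
  chrom <- as.character(seqnames(gr))
  if (!chrom %in% names(track))
    stopf("interval chromosome %s not covered by the conservation track", chrom)
  v <- track[[chrom]]
  if (end(gr) > length(v) || start(gr) < 1)
    stopf("interval [%d, %d) outside the %s track extent (%d bases)",
          start(gr) - 1L, end(gr), chrom, length(v))
  mean_score <- mean(as.numeric(window(v, start(gr), end(gr))))
  list(mean_score = mean_score, passes = mean_score > threshold)
}

#' Map an interval through a block table
#'
#' Translates coordinates through an ordered table of source-to-target
#' alignment blocks (a lightweight stand-in for chain-file liftover between
#' assemblies). The interval must be covered by a single block for at least
#' `min_coverage` of its width (default: completely); the covering block's
#' offset is applied. An identity mapping (`mapping = NULL`) returns the
#' input, which supports single-assembly runs.
#'
#' @param interval Single-range `GRanges`.
#' @param mapping `data.frame` with columns `src_chrom`, `src_start`,
#'   `src_end`, `tgt_chrom`, `tgt_start` (0-based half-open; blocks
#'   non-overlapping in source), or `NULL` for identity.
#' @param min_coverage Minimum fraction of the interval a single block must
#'   cover (default 1.0).
#' @return Mapped `GRanges`, or `NULL` when no block qualifies.
#' @export
map_interval <- function(interval, mapping = NULL, min_coverage = 1.0) {
  gr <- as_dmr_granges(interval)
  stopifnot(length(gr) == 1L)
  if (is.null(mapping)) return(gr)
  need <- c("src_chrom", "src_start", "src_end", "tgt_chrom", "tgt_start")
  if (!all(need %in% colnames(mapping)))
    stopf("malformed mapping table: need columns %s", paste(need, collapse = ", "))
  if (any(mapping$src_end <= mapping$src_start))
    stopf("malformed mapping table: empty or inverted source block")
  src <- GRanges(mapping$src_chrom,
                 IRanges(mapping$src_start + 1L, mapping$src_end))
  if (!isDisjoint(src))
    stopf("malformed mapping table: source blocks overlap")
  ov <- findOverlaps(gr, src)
  if (!length(ov)) return(NULL)
  covered <- width(pintersect(rep(gr, length(ov)), src[subjectHits(ov)]))
  best <- which.max(covered)
  if (covered[best] < min_coverage * width(gr)) return(NULL)
  blk <- subjectHits(ov)[best]
  offset <- mapping$tgt_start[blk] - mapping$src_start[blk]
  GRanges(mapping$tgt_chrom[blk],
          IRanges(start(gr) + offset, end(gr) + offset))
}

#' Link a DMR to genes through its containing TAD
#'
#' Within a window of `window` bases either side of the (mapped) DMR, finds
#' the topologically associating domain that fully contains the DMR — the
#' smallest one if TADs are nested — and reports every gene whose body
#' overlaps that TAD as being in contact with the DMR. A DMR contained by
#' no TAD (including one spanning a TAD boundary) yields no linked genes.
#'
#' @param dmr Single-range `GRanges`.
#' @param tads `GRanges` of TADs.
#' @param genes `GRanges` with a `gene_id` column.
#' @param window Search window in bases (default 1e6).
#' @return List with `dmr`, `tad` (`GRanges` or `NULL`) and `contact_genes`
#'   (character vector, possibly empty).
#' @export
link_dmr_to_genes <- function(dmr, tads, genes, window = 1e6) {
  gr <- as_dmr_granges(dmr)
  stopifnot(length(gr) == 1L)
  search <- suppressWarnings(trim(resize(gr, width(gr) + 2 * window, fix = "center")))
  cand <- tads[overlapsAny(tads, search, ignore.strand = TRUE)]
  containing <- cand[start(cand) <= start(gr) & end(cand) >= end(gr)]
  if (!length(containing) ||
      !any(as.character(seqnames(containing)) == as.character(seqnames(gr)))) {
    return(list(dmr = gr, tad = NULL, contact_genes = character()))
  }
  containing <- containing[as.character(seqnames(containing)) ==
                           as.character(seqnames(gr))]
  tad <- containing[which.min(width(containing))]
  hit <- overlapsAny(genes, tad, ignore.strand = TRUE)
  list(dmr = gr, tad = tad, contact_genes = unique(genes$gene_id[hit]))
}

#' Conservation-filtered TAD linkage of intergenic DMRs
#'
#' The intergenic-DMR procedure end to end: each DMR is kept only if its
#' mean conservation exceeds `cons_threshold`; surviving DMRs are mapped
#' through `mapping` (identity when `NULL`) and linked to genes via their
#' containing TAD.
#'
#' @param dmrs `GRanges` or `data.frame` of (typically intergenic) DMRs.
#' @param track Conservation `RleList`.
#' @param tads,genes See [link_dmr_to_genes()].
#' @param mapping Optional block table for cross-assembly transfer.
#' @param cons_threshold Strict mean-conservation cutoff (default 0.5).
#' @param window TAD search window (default 1e6).
#' @return `data.frame` with one row per input DMR: coordinates,
#'   `mean_conservation`, `conserved`, `mapped`, `tad_start`/`tad_end`
#'   (NA when none) and a list-column `contact_genes`.
#' @export
link_intergenic_dmrs <- function(dmrs, track, tads, genes, mapping = NULL,
                                 cons_threshold = 0.5, window = 1e6) {
  gr <- as_dmr_granges(dmrs)
  rows <- lapply(seq_along(gr), function(i) {
    cons <- mean_conservation(gr[i], track, cons_threshold)
    row <- data.frame(chrom = as.character(seqnames(gr[i])),
                      start = start(gr[i]) - 1L, end = end(gr[i]),
                      mean_conservation = cons$mean_score,
                      conserved = cons$passes, mapped = FALSE,
                      tad_start = NA_integer_, tad_end = NA_integer_,
                      contact_genes = I(list(character())),
                      stringsAsFactors = FALSE)
    if (!cons$passes) return(row)
    mapped <- map_interval(gr[i], mapping)
    if (is.null(mapped)) return(row)
    row$mapped <- TRUE
    link <- link_dmr_to_genes(mapped, tads, genes, window)
    if (!is.null(link$tad)) {
      row$tad_start <- start(link$tad) - 1L
      row$tad_end <- end(link$tad)
      row$contact_genes <- I(list(link$contact_genes))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
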