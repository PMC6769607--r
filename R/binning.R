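#' Partition chromosomes into fixed-width bins
#'
#' Tiles each chromosome from offset 0 in steps of `width`; the terminal bin
#' is truncated at the chromosome end. Bins are the testing unit of the whole
#' analysis (500 bp by default).
#'
#' @param genome_lengths Named integer vector of chromosome lengths, or a
#'   `DNAStringSet` whose widths are used.
#' @param width Bin width in bases (default 500).
#' @return A `GRanges`, sorted by (chromosome, start), with `seqlengths` set.
#' @examples
#' make_bins(c(chr1 = 1200), width = 500)
#' @export
make_bins <- function(genome_lengths, width = 500) {
  if (is(genome_lengths, "DNAStringSet")) {
    genome_lengths <- setNames(Biostrings::width(genome_lengths),
                               names(genome_lengths))
  }
  if (width < 1) stopf("bin width must be >= 1, got %s", width)
  if (is.null(names(genome_lengths)) || any(!nzchar(names(genome_lengths))))
    stopf("genome_lengths must be named by chromosome")
  if (any(genome_lengths <= 0))
    stopf("non-positive chromosome length for %s",
          paste(names(genome_lengths)[genome_lengths <= 0], collapse = ", "))
  genome_lengths <- genome_lengths[order(names(genome_lengths))]
  lens <- as.integer(genome_lengths)
  grl <- lapply(seq_along(lens), function(i) {
    starts <- seq.int(0L, lens[i] - 1L, by = width)
    ends <- pmin(starts + width, lens[i])
    GRanges(names(genome_lengths)[i], IRanges(starts + 1L, ends))
  })
  gr <- sort(suppressWarnings(do.call(c, grl)))
  seqlengths(gr) <- genome_lengths[seqlevels(gr)]
  gr
}

#' CpG and MRE-site content of a sequence
#'
#' Counts CG dinucleotides and occurrences of any MRE recognition motif in a
#' single sequence (typically one bin). Occurrences of distinct motifs are
#' counted independently, so overlapping sites of different enzymes each
#' count; `N` bases never match.
#'
#' @param sequence A `DNAString`, `DNAStringSet` of length 1, or character
#'   scalar over `{A,C,G,T,N}`.
#' @param mre_motifs Character vector of recognition motifs
#'   (default `c("CCGG", "GCGC", "CCGC")`, HpaII/Hin6I/AciI-style).
#' @return Named integer vector `c(cpg_count, mre_site_count)`.
#' @examples
#' bin_content("CCGGCCGG")
#' @export
bin_content <- function(sequence, mre_motifs = c("CCGG", "GCGC", "CCGC")) {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  if (is(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    sequence <- sequence[[1L]]
  }
  if (length(mre_motifs) == 0L || any(!nzchar(mre_motifs)))
    stopf("mre_motifs must be a non-empty set of non-empty strings")
  cpg <- Biostrings::countPattern("CG", sequence)
  mre <- sum(vapply(mre_motifs, function(m)
    Biostrings::countPattern(m, sequence), integer(1)))
  c(cpg_count = cpg, mre_site_count = as.integer(mre))
}

#' Per-bin CpG and MRE-site content across a genome
#'
#' Counts each CG dinucleotide and each MRE motif occurrence once, assigned
#' to the bin containing its leftmost base. A site spanning a bin boundary
#' therefore belongs to the left bin, which makes per-bin counts add up to
#' the per-chromosome totals.
#'
#' @param genome Named `DNAStringSet`.
#' @param bins `GRanges` from [make_bins()].
#' @inheritParams bin_content
#' @return `bins` with metadata columns `cpg` and `mre_sites`.
#' @export
compute_bin_content <- function(genome, bins,
                                mre_motifs = c("CCGG", "GCGC", "CCGC")) {
  if (length(mre_motifs) == 0L || any(!nzchar(mre_motifs)))
    stopf("mre_motifs must be a non-empty set of non-empty strings")
  cpg <- integer(length(bins))
  mre <- integer(length(bins))
  for (chrom in seqlevels(bins)) {
    idx <- which(as.character(seqnames(bins)) == chrom)
    if (!length(idx)) next
    seq <- genome[[chrom]]
    starts_cg <- start(matchPattern("CG", seq))
    starts_mre <- sort(unlist(lapply(mre_motifs, function(m)
      start(matchPattern(m, seq)))))
    brk <- c(start(bins)[idx], max(end(bins)[idx]) + 1L)
    cpg[idx] <- as.integer(table(cut(starts_cg, brk, right = FALSE)))
    mre[idx] <- as.integer(table(cut(starts_mre, brk, right = FALSE)))
  }
  bins$cpg <- cpg
  bins$mre_sites <- mre
  bins
}

#' Assign reads to bins
#'
#' Each read is assigned to exactly one bin, by default by its 5'-most
#' coordinate (the start for `+`/unstranded reads, the last base for `-`
#' reads); `rule = "midpoint"` uses the read midpoint instead. Reads whose
#' anchor base falls outside every bin are dropped and counted.
#'
#' @param read_intervals `GRanges` of read alignments.
#' @param bins Sorted, non-overlapping `GRanges` of bins.
#' @param rule `"five_prime"` (default) or `"midpoint"`.
#' @return List with `counts` (integer per bin) and `dropped` (number of
#'   reads outside all bins).
#' @export
assign_reads <- function(read_intervals, bins, rule = c("five_prime", "midpoint")) {
  rule <- match.arg(rule)
  if (is.unsorted(order(as.factor(seqnames(bins)), start(bins))) ||
      any(start(bins)[-1] <= end(bins)[-length(bins)] &
          as.character(seqnames(bins))[-1] ==
          as.character(seqnames(bins))[-length(bins)]))
    stopf("bins must be sorted and non-overlapping")
  anchor <- if (rule == "five_prime") {
    ifelse(as.character(strand(read_intervals)) == "-",
           end(read_intervals), start(read_intervals))
  } else {
    floor((start(read_intervals) + end(read_intervals)) / 2)
  }
  pts <- GRanges(seqnames(read_intervals), IRanges(anchor, width = 1L))
  # reads on chromosomes absent from the binning are simply dropped
  hits <- suppressWarnings(findOverlaps(pts, bins, select = "first"))
  dropped <- sum(is.na(hits))
  counts <- tabulate(hits[!is.na(hits)], nbins = length(bins))
  list(counts = as.integer(counts), dropped = dropped)
}

#' Build the per-bin count table for two samples
#'
#' Convenience assembly of the table consumed by [mnm_test_all()]: bins with
#' content plus per-sample MeDIP and MRE counts.
#'
#' @param bins `GRanges` with `cpg` and `mre_sites` columns
#'   (see [compute_bin_content()]).
#' @param medip,mre Integer matrices (bins x samples) of read counts.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `cpg`, `mre_sites`, `medip_<i>`, `mre_<i>`.
#' @export
bin_count_table <- function(bins, medip, mre) {
  medip <- as.matrix(medip); mre <- as.matrix(mre)
  stopifnot(nrow(medip) == length(bins), nrow(mre) == length(bins),
            ncol(medip) == ncol(mre))
  if (any(medip < 0) || any(mre < 0)) stopf("negative read counts")
  df <- data.frame(chrom = as.character(seqnames(bins)),
                   start = start(bins) - 1L, end = end(bins),
                   cpg = bins$cpg, mre_sites = bins$mre_sites,
                   stringsAsFactors = FALSE)
  colnames(medip) <- paste0("medip_", seq_len(ncol(medip)))
  colnames(mre) <- paste0("mre_", seq_len(ncol(mre)))
  cbind(df, medip, mre)
}

count_table_assay <- function(counts, assay) {
  cols <- grep(paste0("^", assay, "_[0-9]+$"), colnames(counts), value = TRUE)
  if (!length(cols)) stopf("count table has no %s_* columns", assay)
  cols <- cols[order(as.integer(sub(paste0(assay, "_"), "", cols)))]
  as.matrix(counts[, cols, drop = FALSE])
}
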