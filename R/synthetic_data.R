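# -- sequence simulation helpers --------------------------------------------
#
# Sequences are drawn i.i.d. with a target GC, then CpG dinucleotides are
# thinned: each CG occurrence keeps its G with probability `oe`, otherwise
# the G is replaced by A or T. This gives an observed/expected CpG ratio
# close to `oe` while leaving GC essentially at target.

sim_sequence <- function(len, gc, oe) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ch <- sample(names(p), len, replace = TRUE, prob = p)
  if (oe < 1) {
    cg <- which(ch[-len] == "C" & ch[-1] == "G")
    kill <- cg[runif(length(cg)) > oe]
    if (length(kill))
      ch[kill + 1] <- sample(c("A", "T"), length(kill), replace = TRUE)
  }
  paste(ch, collapse = "")
}

# non-overlapping placements of n intervals of width w in [1, len], with at
# least `margin` bases between them and from the ends; NULL if impossible
place_intervals <- function(n, w, len, margin, max_tries = 200) {
  if (n == 0) return(integer(0))
  for (t in seq_len(max_tries)) {
    starts <- sort(sample.int(len - w - 2 * margin, n) + margin)
    if (n == 1 || all(diff(starts) >= w + margin)) return(starts)
  }
  stopf("could not place %d intervals of width %d in %d bases", n, w, len)
}

#' Generate a synthetic genome with planted CpG islands
#'
#' Background sequence is CpG-depleted (GC 40%, observed/expected CpG ratio
#' about 0.2, mirroring vertebrate genome statistics) so that planted
#' islands are unambiguous. Each island is simulated at the requested GC and
#' O/E, re-tested against the three island criteria (length > 200 bp,
#' GC > 50%, O/E > 0.6) and re-drawn until it satisfies them. MRE motif
#' occurrences are additionally planted uniformly at `mre_per_kb` sites per
#' kilobase so every bin carries MRE-site content.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bases (recycled across
#'   chromosomes); must be at least 10 bin widths.
#' @param island_spec List with `count`, `length`, `gc`, `oe` describing the
#'   planted islands; values violating the island criteria are rejected.
#' @param seed Integer seed; output is byte-identical per seed.
#' @param bin_width Bin width used only for the minimum-length check.
#' @param background List with `gc` and `oe` of the background composition.
#' @param mre_per_kb Planted MRE motif density (sites per kb).
#' @param mre_motifs Motifs planted (and later counted); first motif used
#'   for planting.
#' @return List with `genome` (`DNAStringSet`) and `true_islands`
#'   (`GRanges`).
#' @export
gen_genome <- function(n_chrom, chrom_len,
                       island_spec = list(count = 5, length = 300,
                                          gc = 0.6, oe = 0.75),
                       seed = 1, bin_width = 500,
                       background = list(gc = 0.4, oe = 0.2),
                       mre_per_kb = 10,
                       mre_motifs = c("CCGG", "GCGC", "CCGC")) {
  if (any(chrom_len < 10 * bin_width))
    stopf("chrom_len must be at least 10 bin widths (%d)", 10 * bin_width)
  if (island_spec$count > 0) {
    if (island_spec$length <= 200)
      stopf("island length must be greater than 200 bp, got %d",
            island_spec$length)
    if (island_spec$gc <= 0.5)
      stopf("island GC content must be greater than 0.5, got %g",
            island_spec$gc)
    if (island_spec$oe <= 0.6)
      stopf("island observed/expected CpG ratio must be greater than 0.6, got %g",
            island_spec$oe)
  }
  chrom_len <- rep_len(as.integer(chrom_len), n_chrom)
  with_seed(seed, {
    seqs <- character(n_chrom)
    islands <- GRanges()
    for (i in seq_len(n_chrom)) {
      len <- chrom_len[i]
      s <- sim_sequence(len, background$gc, background$oe)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      # plant MRE motifs with >= 50 bp spacing: each motif is GC-rich and
      # carries a CpG, and unspaced clusters would push background windows
      # over the island thresholds
      n_mre <- round(mre_per_kb * len / 1000)
      motif <- strsplit(mre_motifs[1], "", fixed = TRUE)[[1]]
      if (n_mre > 0) {
        cand <- sort(sample.int(len - length(motif), min(3 * n_mre, len %/% 10)))
        pos <- integer(0); last <- -Inf
        for (p in cand) {
          if (p - last >= 50) { pos <- c(pos, p); last <- p }
          if (length(pos) >= n_mre) break
        }
        for (p in pos) ch[p:(p + length(motif) - 1)] <- motif
      }
      # repair pass: composition fluctuations can push isolated background
      # windows over the island thresholds; thin natural (non-motif) CpGs
      # inside any detected segment until the detector is silent, so the
      # background provably sits below the thresholds
      motif_cover <- rep(FALSE, len)
      if (n_mre > 0) for (p in pos)
        motif_cover[p:(p + length(motif) - 1)] <- TRUE
      for (rep_it in 1:25) {
        det <- find_islands_one(DNAString(paste(ch, collapse = "")),
                                201, 0.5, 0.6)
        if (!length(det)) break
        for (k in seq_along(det)) {
          span <- start(det)[k]:(end(det)[k] - 1L)
          cg <- span[ch[span] == "C" & ch[span + 1L] == "G" &
                     !motif_cover[span] & !motif_cover[span + 1L]]
          if (length(cg))
            ch[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
        }
      }
      # plant islands, each re-verified against the detector's criteria
      if (island_spec$count > 0) {
        starts <- place_intervals(island_spec$count, island_spec$length, len,
                                  margin = 1000)
        for (st in starts) {
          repeat {
            isl <- strsplit(sim_sequence(island_spec$length, island_spec$gc,
                                         island_spec$oe), "", fixed = TRUE)[[1]]
            cums <- seq_cumsums(paste(isl, collapse = ""))
            ok <- island_criteria_ok(
              island_window_stats(cums, 1L, island_spec$length),
              201, 0.5, 0.6)
            if (ok) break
          }
          ch[st:(st + island_spec$length - 1)] <- isl
        }
        islands <- c(islands, GRanges(paste0("chr", i),
                                      IRanges(starts, width = island_spec$length)))
      }
      seqs[i] <- paste(ch, collapse = "")
    }
    genome <- DNAStringSet(setNames(seqs, paste0("chr", seq_len(n_chrom))))
    if (length(islands))
      seqlengths(islands) <- setNames(chrom_len,
                                      paste0("chr", seq_len(n_chrom)))[seqlevels(islands)]
    list(genome = genome, true_islands = islands)
  })
}

#' Generate gene models, TADs and a conservation track
#'
#' Genes are non-overlapping intervals with random strand; TADs tile a
#' configurable fraction of each chromosome without overlapping; the
#' conservation track is a per-base score in `[0, 1]` made of low-score
#' background (Beta-distributed, piecewise constant) plus high-score blocks
#' (around 0.9) covering a configurable number of intergenic bins.
#'
#' @param genome Named `DNAStringSet` (from [gen_genome()]).
#' @param n_genes,n_tads Numbers of genes and TADs per chromosome.
#' @param seed Integer seed.
#' @param gene_width,tad_fraction Gene width in bases; fraction of each
#'   chromosome covered by TADs.
#' @param n_conserved_bins High-conservation blocks planted per chromosome,
#'   each one `bin_width` wide and outside genes.
#' @param bin_width Width of the conserved blocks (matches the analysis bin
#'   width).
#' @return List with `genes` (`GRanges` with `gene_id`, strand), `tads`
#'   (`GRanges`), `conservation` (`RleList`, one numeric run-length vector
#'   per chromosome) and `conserved_blocks` (`GRanges`).
#' @export
gen_annotation_truth <- function(genome, n_genes, n_tads, seed = 1,
                                 gene_width = 3000, tad_fraction = 0.6,
                                 n_conserved_bins = 2, bin_width = 500) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(gene_width > lens))
    stopf("gene of width %d does not fit in the shortest chromosome (%d bp)",
          gene_width, min(lens))
  if (n_tads < 0) stopf("n_tads must be >= 0")
  with_seed(seed, {
    genes <- GRanges(); tads <- GRanges(); blocks <- GRanges()
    cons <- list()
    for (chrom in names(genome)) {
      len <- lens[[chrom]]
      if (n_genes > 0) {
        gs <- place_intervals(n_genes, gene_width, len, margin = 2 * bin_width)
        g <- GRanges(chrom, IRanges(gs, width = gene_width),
                     strand = sample(c("+", "-"), n_genes, replace = TRUE))
        g$gene_id <- paste0(chrom, "_g", seq_len(n_genes))
        genes <- c(genes, g)
      }
      if (n_tads > 0) {
        tw <- floor(len * tad_fraction / n_tads)
        gap <- floor((len - tw * n_tads) / (n_tads + 1))
        ts <- gap + (seq_len(n_tads) - 1) * (tw + gap) + 1
        tads <- c(tads, GRanges(chrom, IRanges(ts, width = tw)))
      }
      # background: piecewise-constant Beta(1, 9) over 50 bp segments
      nseg <- ceiling(len / 50)
      score <- rep(round(rbeta(nseg, 1, 9), 3), each = 50)[seq_len(len)]
      if (n_conserved_bins > 0) {
        cand <- make_bins(setNames(len, chrom), width = bin_width)
        cand <- cand[width(cand) == bin_width]
        if (n_genes > 0)
          cand <- cand[!overlapsAny(cand, genes, ignore.strand = TRUE)]
        pick <- cand[sample.int(length(cand), min(n_conserved_bins, length(cand)))]
        for (k in seq_along(pick))
          score[start(pick)[k]:end(pick)[k]] <- round(runif(1, 0.85, 0.95), 3)
        blocks <- c(blocks, pick)
      }
      cons[[chrom]] <- Rle(score)
    }
    sl <- lens
    if (length(genes)) seqlengths(genes) <- sl[seqlevels(genes)]
    if (length(tads)) seqlengths(tads) <- sl[seqlevels(tads)]
    if (length(blocks)) seqlengths(blocks) <- sl[seqlevels(blocks)]
    list(genes = genes, tads = tads,
         conservation = as(cons, "RleList"), conserved_blocks = blocks)
  })
}

#' Plant true methylation levels and DMRs
#'
#' All bins share a common baseline methylation in both groups; exactly
#' `round(dmr_frac * n_bins)` bins are made differentially methylated, with
#' group 2 shifted by `+delta` or `-delta` (direction Bernoulli(0.5) from
#' the seed stream).
#'
#' @param n_bins Number of bins (or a `GRanges` of bins, whose length is
#'   used).
#' @param dmr_frac Fraction of bins planted as DMRs, in `[0, 1]`.
#' @param delta Methylation difference of planted DMRs, in `(0, 1]`.
#' @param base_m Baseline methylation level in `(0, 1)`; `base_m + delta`
#'   and `base_m - delta` are clamped to `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `m` (bins x 2 matrix of true methylation),
#'   `dmr_bins` (integer indices) and `dmr_direction`
#'   (`"group1-higher"`/`"group2-higher"` per planted DMR).
#' @export
gen_methylome <- function(n_bins, dmr_frac, delta, base_m = 0.5, seed = 1) {
  if (is(n_bins, "GRanges")) n_bins <- length(n_bins)
  if (dmr_frac < 0 || dmr_frac > 1) stopf("dmr_frac must be in [0, 1]")
  if (delta <= 0 || delta > 1) stopf("delta must be in (0, 1]")
  if (base_m <= 0 || base_m >= 1) stopf("base_m must be in (0, 1)")
  with_seed(seed, {
    m <- matrix(base_m, n_bins, 2, dimnames = list(NULL, c("group1", "group2")))
    n_dmr <- round(dmr_frac * n_bins)
    idx <- sort(sample.int(n_bins, n_dmr))
    up <- rbinom(n_dmr, 1, 0.5) == 1
    m[idx, 2] <- pmin(1, pmax(0, base_m + ifelse(up, delta, -delta)))
    list(m = m, dmr_bins = idx,
         dmr_direction = ifelse(up, "group2-higher", "group1-higher"))
  })
}

#' Simulate per-bin MeDIP and MRE read counts
#'
#' MeDIP counts for sample `i` in bin `b` are Poisson with rate
#' `s_i * c_b * m_bi * kappa_medip`; MRE counts are Poisson with rate
#' `s_i * r_b * (1 - m_bi) * kappa_mre`, where `c_b`/`r_b` are the bin's
#' CpG and MRE-site content and each assay's `kappa` is set so that the
#' mean simulated count per bin equals `mean_depth`.
#'
#' @param m Bins x 2 matrix of true methylation (see [gen_methylome()]).
#' @param cpg,mre_sites Integer vectors of bin content.
#' @param library_sizes List with numeric length-2 vectors `medip` and
#'   `mre`: relative library sizes of the two samples (defaults drawn in
#'   1.0-1.3 to exercise normalisation).
#' @param mean_depth Target mean reads per bin per sample (per assay).
#' @param seed Integer seed.
#' @return Count table as from [bin_count_table()] minus coordinates:
#'   columns `cpg`, `mre_sites`, `medip_1`, `medip_2`, `mre_1`, `mre_2`.
#' @export
gen_counts <- function(m, cpg, mre_sites, library_sizes = NULL,
                       mean_depth = 30, seed = 1) {
  if (mean_depth <= 0) stopf("mean_depth must be positive")
  n <- nrow(m)
  stopifnot(length(cpg) == n, length(mre_sites) == n)
  with_seed(seed, {
    library_sizes <- library_sizes %||%
      list(medip = runif(2, 1.0, 1.3), mre = runif(2, 1.0, 1.3))
    k_medip <- if (mean(cpg * m) > 0) mean_depth / mean(cpg * m) else 0
    k_mre <- if (mean(mre_sites * (1 - m)) > 0)
      mean_depth / mean(mre_sites * (1 - m)) else 0
    medip <- sapply(1:2, function(i)
      rpois(n, library_sizes$medip[i] * cpg * m[, i] * k_medip))
    mre <- sapply(1:2, function(i)
      rpois(n, library_sizes$mre[i] * mre_sites * (1 - m[, i]) * k_mre))
    colnames(medip) <- c("medip_1", "medip_2")
    colnames(mre) <- c("mre_1", "mre_2")
    out <- data.frame(cpg = cpg, mre_sites = mre_sites, medip, mre)
    attr(out, "library_sizes") <- library_sizes
    out
  })
}

#' Simulate MSP and qPCR validation measurements
#'
#' Methylation-specific PCR: per CpG site and animal, methylated and
#' unmethylated template quantities whose ratio `M/(M+U)` is centred on the
#' site's true methylation, with multiplicative log-normal noise of the
#' given coefficient of variation. Expression: per gene and animal, a target
#' quantity (group 2 scaled by `fold_change`) and three housekeeping
#' quantities, all log-normal.
#'
#' @param sites Data frame with `site` and `true_m` (true methylation per
#'   site, shared by both groups unless `true_m2` is given).
#' @param genes Character vector of gene names for expression measurements.
#' @param n_animals Animals per group (>= 2).
#' @param noise Coefficient of variation of the multiplicative noise.
#' @param fold_change Group-2/group-1 expression ratio (1 = null).
#' @param seed Integer seed.
#' @return List with data frames `msp` (`site`, `animal`, `group`,
#'   `methylated_quantity`, `unmethylated_quantity`) and `expression`
#'   (`gene`, `animal`, `group`, `target`, `hk1`-`hk3`).
#' @export
gen_validation_data <- function(sites, genes = character(), n_animals = 6,
                                noise = 0.1, fold_change = 1, seed = 1) {
  if (n_animals < 2) stopf("n_animals must be >= 2 for group comparisons")
  sdlog <- sqrt(log(1 + noise^2))
  with_seed(seed, {
    grid <- expand.grid(site = sites$site, animal = seq_len(2 * n_animals),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$group <- ifelse(grid$animal <= n_animals, "group1", "group2")
    tm <- sites$true_m[match(grid$site, sites$site)]
    if (!is.null(sites$true_m2))
      tm[grid$group == "group2"] <-
        sites$true_m2[match(grid$site, sites$site)][grid$group == "group2"]
    nz <- function(n) if (sdlog > 0) exp(rnorm(n, -sdlog^2 / 2, sdlog)) else rep(1, n)
    msp <- data.frame(grid,
                      methylated_quantity = tm * nz(nrow(grid)),
                      unmethylated_quantity = (1 - tm) * nz(nrow(grid)))
    expression <- NULL
    if (length(genes)) {
      eg <- expand.grid(gene = genes, animal = seq_len(2 * n_animals),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      eg$group <- ifelse(eg$animal <= n_animals, "group1", "group2")
      base <- ifelse(eg$group == "group2", fold_change, 1)
      expression <- data.frame(eg,
                               target = base * nz(nrow(eg)),
                               hk1 = nz(nrow(eg)), hk2 = nz(nrow(eg)),
                               hk3 = nz(nrow(eg)))
    }
    list(msp = msp, expression = expression)
  })
}

#' Simulate a complete two-group methylome study
#'
#' Composes [gen_genome()], [gen_annotation_truth()], [gen_methylome()] and
#' [gen_counts()] into one bundle carrying every input the pipeline needs
#' plus the planted truth. Sub-seeds are derived deterministically from
#' `seed`.
#'
#' @param seed Integer master seed.
#' @param n_chrom,chrom_len Genome shape.
#' @param island_spec Planted-island specification (see [gen_genome()]).
#' @param n_genes,n_tads Per-chromosome annotation counts.
#' @param dmr_frac,delta,base_m Methylome truth (see [gen_methylome()]).
#' @param mean_depth Mean reads per bin per sample and assay.
#' @param bin_width Analysis bin width.
#' @param library_sizes Optional per-assay library sizes.
#' @param mre_motifs MRE recognition motifs.
#' @return List with `genome`, `bins` (content-annotated `GRanges`),
#'   `counts` (count table with coordinates), `truth` (islands, genes,
#'   TADs, conservation, methylation matrix, DMR indices/directions,
#'   library sizes) and the generation `params`.
#' @export
simulate_methylome_study <- function(seed = 1, n_chrom = 1, chrom_len = 200000,
                                     island_spec = list(count = 5, length = 300,
                                                        gc = 0.6, oe = 0.75),
                                     n_genes = 8, n_tads = 3,
                                     dmr_frac = 0.1, delta = 0.5, base_m = 0.5,
                                     mean_depth = 30, bin_width = 500,
                                     library_sizes = NULL,
                                     mre_motifs = c("CCGG", "GCGC", "CCGC")) {
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1, 4))
  gen <- gen_genome(n_chrom, chrom_len, island_spec, seed = sub[1],
                    bin_width = bin_width, mre_motifs = mre_motifs)
  ann <- gen_annotation_truth(gen$genome, n_genes, n_tads, seed = sub[2],
                              bin_width = bin_width)
  bins <- compute_bin_content(gen$genome, make_bins(gen$genome, bin_width),
                              mre_motifs)
  meth <- gen_methylome(length(bins), dmr_frac, delta, base_m, seed = sub[3])
  cnt <- gen_counts(meth$m, bins$cpg, bins$mre_sites,
                    library_sizes = library_sizes, mean_depth = mean_depth,
                    seed = sub[4])
  counts <- cbind(data.frame(chrom = as.character(seqnames(bins)),
                             start = start(bins) - 1L, end = end(bins),
                             stringsAsFactors = FALSE),
                  cnt)
  list(genome = gen$genome, bins = bins, counts = counts,
       truth = list(islands = gen$true_islands, genes = ann$genes,
                    tads = ann$tads, conservation = ann$conservation,
                    conserved_blocks = ann$conserved_blocks,
                    m = meth$m, dmr_bins = meth$dmr_bins,
                    dmr_direction = meth$dmr_direction,
                    library_sizes = attr(cnt, "library_sizes")),
       params = list(seed = seed, n_chrom = n_chrom, chrom_len = chrom_len,
                     island_spec = island_spec, n_genes = n_genes,
                     n_tads = n_tads, dmr_frac = dmr_frac, delta = delta,
                     base_m = base_m, mean_depth = mean_depth,
                     bin_width = bin_width))
}
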