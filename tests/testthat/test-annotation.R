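# character-level island statistics, independent of the detector internals
oracle_island_stats <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  nC <- sum(ch == "C"); nG <- sum(ch == "G")
  nCG <- oracle_count_occurrences(s, "CG")
  list(len = nchar(s), gc = (nC + nG) / nchar(s),
       oe = if (nC * nG > 0) nCG * nchar(s) / (nC * nG) else 0)
}

test_that("extreme compositions give the expected island calls", {
  cg <- paste(rep("CG", 250), collapse = "")
  isl <- find_cpg_islands(cg)
  expect_equal(length(isl), 1)
  expect_gte(width(isl), 490)
  st <- oracle_island_stats(substr(cg, start(isl), end(isl)))
  expect_equal(st$gc, 1)
  expect_gt(st$oe, 1.9)

  expect_equal(length(find_cpg_islands(strrep("A", 1000))), 0)
  expect_equal(length(find_cpg_islands(strrep("N", 1000))), 0)
})

test_that("emitted islands always re-satisfy the three criteria", {
  study <- simulate_methylome_study(seed = 11, chrom_len = 100000)
  isl <- find_cpg_islands(study$genome)
  expect_gte(length(isl), length(study$truth$islands))
  s <- as.character(study$genome[[1]])
  for (k in seq_along(isl)) {
    st <- oracle_island_stats(substr(s, start(isl)[k], end(isl)[k]))
    expect_gt(st$len, 200)
    expect_gt(st$gc, 0.5)
    expect_gt(st$oe, 0.6)
  }
})

test_that("planted islands are recovered with reciprocal overlap", {
  study <- simulate_methylome_study(seed = 12, chrom_len = 150000)
  isl <- find_cpg_islands(study$genome)
  tru <- study$truth$islands
  hits <- findOverlaps(tru, isl)
  ov <- width(pintersect(tru[queryHits(hits)], isl[subjectHits(hits)]))
  best <- tapply(ov, queryHits(hits), max)
  expect_equal(length(best), length(tru))
  expect_true(all(best >= 0.5 * width(tru)))
  # nothing called far away from any planted island
  expect_equal(sum(countOverlaps(isl, tru + 100) == 0), 0)
})

test_that("shores flank islands, clip at ends, and never overlap islands", {
  isl <- GRanges("chr1", IRanges(10001, 10300))  # 0-based [10000, 10300)
  sh <- derive_shores(isl, genome_lengths = c(chr1 = 1e6))
  expect_equal(start(sh) - 1L, c(8000L, 10300L))
  expect_equal(end(sh), c(10000L, 12300L))

  at_start <- GRanges("chr1", IRanges(1, 250))
  sh2 <- derive_shores(at_start, genome_lengths = c(chr1 = 1e6))
  expect_equal(length(sh2), 1)
  expect_equal(start(sh2) - 1L, 250L)

  # islands 1,500 bp apart: the inter-island gap becomes one merged shore
  pair <- GRanges("chr1", IRanges(c(5001, 6801), width = 300))
  sh3 <- derive_shores(pair, genome_lengths = c(chr1 = 1e6))
  expect_false(any(overlapsAny(sh3, pair)))
  gap <- sh3[start(sh3) > 5300 & end(sh3) < 6801]
  expect_equal(length(gap), 1)
  expect_equal(c(start(gap), end(gap)), c(5301, 6800))

  # brute-force per-base check: shore bases = union of flanks minus islands
  set.seed(13)
  ril <- reduce(GRanges("chr1", IRanges(sort(sample(5000, 4) * 7 + 1000),
                                        width = sample(200:400, 4))))
  shr <- derive_shores(ril, flank = 500, genome_lengths = c(chr1 = 50000))
  base <- rep(FALSE, 50000)
  for (k in seq_along(ril)) {
    base[max(1, start(ril)[k] - 500):(start(ril)[k] - 1)] <- TRUE
    base[(end(ril)[k] + 1):min(50000, end(ril)[k] + 500)] <- TRUE
  }
  for (k in seq_along(ril)) base[start(ril)[k]:end(ril)[k]] <- FALSE
  got <- rep(FALSE, 50000)
  for (k in seq_along(shr)) got[start(shr)[k]:end(shr)[k]] <- TRUE
  expect_identical(got, base)
})

test_that("context labels follow the documented precedence", {
  islands <- GRanges("chr1", IRanges(20001, 20500))
  shores <- derive_shores(islands, genome_lengths = c(chr1 = 1e6))
  genes <- GRanges("chr1", IRanges(c(50001, 58001), width = 5000),
                   strand = c("+", "-"))
  genes$gene_id <- c("gA", "gB")

  lab <- function(s, e) annotate_dmrs(
    data.frame(chrom = "chr1", start = s, end = e),
    islands, shores, genes)

  expect_identical(lab(52000, 52500)$gene_context, "intragenic")
  # 0-based [49000, 49500) sits inside gA's 1500 bp upstream flank
  expect_identical(lab(49000, 49500)$gene_context, "promoter")
  # past gA's TES (+ strand): downstream
  expect_identical(lab(55200, 55700)$gene_context, "downstream")
  # gB is on -, so its promoter flank lies right of its end
  expect_identical(lab(63500, 64000)$gene_context, "promoter")
  expect_identical(lab(900000, 900500)$gene_context, "intergenic")

  # a region overlapping one gene's downstream flank and another's promoter
  # takes the promoter label
  pair <- GRanges("chr1", IRanges(c(50001, 56001), width = 5000),
                  strand = c("+", "+"))
  pair$gene_id <- c("gC", "gD")   # gD promoter [54500, 56000) overlaps gC
                                  # downstream [55000, 56500)
  both <- annotate_dmrs(data.frame(chrom = "chr1", start = 55000, end = 55500),
                        islands, shores, pair)
  expect_identical(both$gene_context, "promoter")

  expect_identical(lab(20100, 20200)$island_context, "island")
  expect_identical(lab(19000, 19500)$island_context, "shore")
  expect_identical(lab(20400, 20600)$island_context, "island")  # precedence
  expect_identical(lab(900000, 900500)$island_context, "open")

  # flipping every strand exchanges promoter and downstream labels
  flipped <- genes
  strand(flipped) <- ifelse(as.character(strand(genes)) == "+", "-", "+")
  expect_identical(annotate_dmrs(data.frame(chrom = "chr1", start = 49000,
                                            end = 49500),
                                 islands, shores, flipped)$gene_context,
                   "downstream")
})

test_that("context summaries partition the DMR set and percentages total 100", {
  ann <- data.frame(
    gene_context = rep(c("intergenic", "intragenic", "promoter", "downstream"),
                       c(82, 52, 5, 4)),
    island_context = rep(c("island", "shore", "open"), c(17, 43, 83)))
  sm <- summarize_contexts(ann)
  expect_equal(sm$total, 143)
  expect_equal(sum(sm$gene_context$percent), 100, tolerance = 0.2)
  expect_equal(sum(sm$island_context$percent), 100, tolerance = 0.2)

  expect_warning(sm0 <- summarize_contexts(ann[0, , drop = FALSE]), "empty")
  expect_equal(sm0$gene_context$percent, rep(0, 4))

  set.seed(14)
  rand <- data.frame(
    gene_context = sample(c("intergenic", "intragenic", "promoter", "downstream"),
                          213, replace = TRUE),
    island_context = sample(c("island", "shore", "open"), 213, replace = TRUE))
  smr <- summarize_contexts(rand)
  expect_equal(sum(smr$gene_context$count), 213)
  expect_equal(sum(smr$gene_context$percent), 100, tolerance = 0.2)
})
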