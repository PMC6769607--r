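test_that("genome generation is seed-deterministic and validates island specs", {
  spec <- list(count = 3, length = 300, gc = 0.6, oe = 0.75)
  g1 <- gen_genome(1, 50000, spec, seed = 5)
  g2 <- gen_genome(1, 50000, spec, seed = 5)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$true_islands, g2$true_islands)
  g3 <- gen_genome(1, 50000, spec, seed = 6)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))

  expect_error(gen_genome(1, 50000, list(count = 2, length = 150,
                                         gc = 0.6, oe = 0.75)),
               "200 bp")
  expect_error(gen_genome(1, 50000, list(count = 2, length = 300,
                                         gc = 0.45, oe = 0.75)),
               "GC")
  expect_error(gen_genome(1, 50000, list(count = 2, length = 300,
                                         gc = 0.6, oe = 0.5)),
               "observed/expected")
  expect_error(gen_genome(1, 2000, spec), "10 bin widths")
})

test_that("planted islands are detectable and the background is silent", {
  spec <- list(count = 5, length = 300, gc = 0.6, oe = 0.75)
  g <- gen_genome(1, 50000, spec, seed = 7)
  found <- find_cpg_islands(g$genome)
  expect_gte(length(found), 5)
  hits <- findOverlaps(g$true_islands, found)
  ov <- width(pintersect(g$true_islands[queryHits(hits)], found[subjectHits(hits)]))
  expect_true(all(tapply(ov, queryHits(hits), max) >= 0.5 * width(g$true_islands)))
  expect_equal(sum(countOverlaps(found, g$true_islands + 100) == 0), 0)

  g0 <- gen_genome(1, 50000, list(count = 0, length = 300, gc = 0.6, oe = 0.75),
                   seed = 1)
  expect_equal(length(find_cpg_islands(g0$genome)), 0)
})

test_that("annotation truth has the requested structure", {
  g <- gen_genome(1, 50000, list(count = 0, length = 300, gc = 0.6, oe = 0.75),
                  seed = 3)
  ann <- gen_annotation_truth(g$genome, n_genes = 3, n_tads = 2, seed = 3)
  expect_equal(length(ann$genes), 3)
  expect_equal(length(ann$tads), 2)
  expect_true(isDisjoint(ann$tads))
  expect_true(all(as.character(strand(ann$genes)) %in% c("+", "-")))
  v <- as.numeric(ann$conservation$chr1)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(length(v), 50000)
  # planted high-score blocks re-test above the conservation threshold
  for (k in seq_along(ann$conserved_blocks))
    expect_gt(mean_conservation(ann$conserved_blocks[k],
                                ann$conservation)$mean_score, 0.5)
  # no TADs requested: downstream linkage finds nothing
  ann0 <- gen_annotation_truth(g$genome, n_genes = 3, n_tads = 0, seed = 3)
  expect_equal(length(ann0$tads), 0)
  l <- link_dmr_to_genes(GRanges("chr1", IRanges(1001, 1500)), ann0$tads,
                         ann0$genes)
  expect_null(l$tad)
  expect_error(gen_annotation_truth(g$genome, 2, 1, gene_width = 60000), "fit")
})

test_that("methylome truth plants the requested DMR set", {
  mt <- gen_methylome(1000, dmr_frac = 0.1, delta = 0.4, base_m = 0.5, seed = 11)
  expect_equal(length(mt$dmr_bins), 100)
  expect_true(all(mt$m >= 0 & mt$m <= 1))
  d <- mt$m[, 2] - mt$m[, 1]
  expect_true(all(abs(d[mt$dmr_bins]) == 0.4))
  expect_true(all(d[-mt$dmr_bins] == 0))
  up <- mt$dmr_bins[mt$dmr_direction == "group2-higher"]
  expect_true(all(d[up] == 0.4))

  null <- gen_methylome(500, dmr_frac = 0, delta = 0.4, seed = 2)
  expect_identical(null$m[, 1], null$m[, 2])
  expect_error(gen_methylome(100, dmr_frac = 2, delta = 0.4), "dmr_frac")
})

test_that("simulated counts follow the Poisson rates", {
  # boundary methylation silences the corresponding assay
  m0 <- matrix(0, 200, 2)
  c0 <- gen_counts(m0, rep(5, 200), rep(3, 200), mean_depth = 30, seed = 3)
  expect_true(all(c0$medip_1 == 0 & c0$medip_2 == 0))
  m1 <- matrix(1, 200, 2)
  c1 <- gen_counts(m1, rep(5, 200), rep(3, 200), mean_depth = 30, seed = 3)
  expect_true(all(c1$mre_1 == 0 & c1$mre_2 == 0))

  # empirical means track the analytic rates within 5%
  set.seed(12)
  cb <- pmax(1, rpois(10000, 9)); rb <- pmax(1, rpois(10000, 5))
  m <- matrix(0.5, 10000, 2)
  sizes <- list(medip = c(1, 1.2), mre = c(1.1, 1))
  cnt <- gen_counts(m, cb, rb, library_sizes = sizes, mean_depth = 30, seed = 5)
  k_medip <- 30 / mean(cb * 0.5)
  expect_equal(mean(cnt$medip_2), mean(1.2 * cb * 0.5 * k_medip),
               tolerance = 0.05)
  k_mre <- 30 / mean(rb * 0.5)
  expect_equal(mean(cnt$mre_1), mean(1.1 * rb * 0.5 * k_mre),
               tolerance = 0.05)
  expect_error(gen_counts(m, cb, rb, mean_depth = -1), "positive")
})

test_that("a full study bundle is deterministic and round-trips through files", {
  s1 <- simulate_methylome_study(seed = 9, chrom_len = 60000, n_genes = 4,
                                 n_tads = 2)
  s2 <- simulate_methylome_study(seed = 9, chrom_len = 60000, n_genes = 4,
                                 n_tads = 2)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$dmr_bins, s2$truth$dmr_bins)

  td <- withr::local_tempdir()
  lens <- setNames(Biostrings::width(s1$genome), names(s1$genome))

  write_genome_fasta(s1$genome, file.path(td, "genome.fa"))
  expect_identical(as.character(read_genome_fasta(file.path(td, "genome.fa"))),
                   as.character(s1$genome))

  write_count_table(s1$counts, file.path(td, "counts.tsv"))
  expect_equal(read_count_table(file.path(td, "counts.tsv")), s1$counts)

  write_gene_models(s1$truth$genes, file.path(td, "genes.tsv"))
  back <- read_gene_models(file.path(td, "genes.tsv"), lens)
  expect_identical(start(back), start(s1$truth$genes))
  expect_identical(as.character(strand(back)), as.character(strand(s1$truth$genes)))
  expect_identical(back$gene_id, s1$truth$genes$gene_id)

  write_bed3(s1$truth$tads, file.path(td, "tads.bed"))
  tads <- read_bed3(file.path(td, "tads.bed"))
  expect_identical(ranges(tads), ranges(s1$truth$tads))

  write_conservation(s1$truth$conservation, file.path(td, "cons.bedGraph"))
  cons <- read_conservation(file.path(td, "cons.bedGraph"), lens)
  expect_equal(as.numeric(cons$chr1), as.numeric(s1$truth$conservation$chr1))

  sets <- list(setA = c("a", "b"), setB = c("c"))
  write_gmt(sets, file.path(td, "sets.gmt"))
  expect_identical(read_gmt(file.path(td, "sets.gmt")), sets)

  write_truth_json(s1, file.path(td, "truth.json"))
  tj <- jsonlite::read_json(file.path(td, "truth.json"), simplifyVector = TRUE)
  expect_equal(tj$dmr_bins, s1$truth$dmr_bins)
  expect_equal(tj$params$seed, 9)
  expect_equal(tj$islands$start, start(s1$truth$islands) - 1L)
  expect_length(tj$library_sizes$medip, 2)
})
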