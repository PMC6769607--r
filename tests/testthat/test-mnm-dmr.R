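unit_factors <- list(medip = c(1, 1), mre = c(1, 1),
                     assay_scale = c(medip = 1, mre = 1))

test_that("size factors equal totals over mean of totals", {
  counts <- data.frame(chrom = "chr1", start = 0, end = 500,
                       cpg = c(5, 5), mre_sites = c(3, 3),
                       medip_1 = c(1e6, 0), medip_2 = c(5e5, 5e5),
                       mre_1 = c(2e5, 2e5), mre_2 = c(4e5, 0))
  f <- size_factors(counts)
  expect_equal(f$medip, c(1, 1))
  expect_equal(f$mre, c(4e5, 4e5) / 4e5)

  counts$medip_1 <- c(2e6, 0); counts$medip_2 <- c(1e6, 0)
  f2 <- size_factors(counts)
  expect_equal(f2$medip, c(4 / 3, 2 / 3))

  set.seed(81)
  tab <- null_count_table(200, seed = 81)$counts
  f3 <- size_factors(tab)
  tot <- c(sum(tab$medip_1), sum(tab$medip_2))
  expect_equal(f3$medip, tot / mean(tot))

  tab$mre_1 <- 0L
  expect_error(size_factors(tab), "mre_1")
})

test_that("the bin test is symmetric and direction follows the estimates", {
  r <- mnm_test(cpg = 5, mre_sites = 5, medip = c(10, 10), mre = c(5, 5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_identical(r$direction, "none")

  # swapping sample labels preserves the p-value and flips the direction
  ra <- mnm_test(cpg = 6, mre_sites = 4, medip = c(12, 3), mre = c(1, 9))
  rb <- mnm_test(cpg = 6, mre_sites = 4, medip = c(3, 12), mre = c(9, 1))
  expect_equal(ra$p_value, rb$p_value, tolerance = 1e-12)
  expect_identical(ra$direction, "group1-higher")
  expect_identical(rb$direction, "group2-higher")

  # published per-gene count patterns: MeDIP up with MRE down marks the
  # group with higher methylation
  map3k5 <- mnm_test(cpg = 5, mre_sites = 5, medip = c(2, 5), mre = c(7, 1))
  expect_identical(map3k5$direction, "group2-higher")
  igf1r <- mnm_test(cpg = 5, mre_sites = 5, medip = c(4, 3), mre = c(1, 2))
  expect_identical(igf1r$direction, "group1-higher")
})

test_that("degenerate bins are handled per the model's conventions", {
  # both-zero content: untested
  r <- mnm_test(cpg = 0, mre_sites = 0, medip = c(0, 0), mre = c(0, 0))
  expect_false(r$tested)
  # content contradicting counts: untested
  r2 <- mnm_test(cpg = 0, mre_sites = 3, medip = c(4, 0), mre = c(1, 1))
  expect_false(r2$tested)
  # tested but read-free: p = 1, no direction
  r3 <- mnm_test(cpg = 5, mre_sites = 2, medip = c(0, 0), mre = c(0, 0))
  expect_true(r3$tested)
  expect_equal(r3$p_value, 1)
  expect_identical(r3$direction, "none")
  # zero MRE reads with positive MeDIP: estimates pinned at 1
  r4 <- mnm_test(cpg = 5, mre_sites = 2, medip = c(30, 4), mre = c(0, 0))
  expect_equal(r4$m1_hat, 1)
  expect_equal(r4$m2_hat, 1)
  expect_error(mnm_test(cpg = 5, mre_sites = 2, medip = c(-1, 4), mre = c(0, 0)),
               "negative")
})

test_that("null estimate of the common methylation equals 1-D ML", {
  set.seed(82)
  env <- asNamespace("medipmre")
  for (i in 1:25) {
    a <- runif(2, 1, 20); b <- runif(2, 1, 20)
    x <- rpois(2, 8); y <- rpois(2, 6)
    if (sum(x) == 0 || sum(y) == 0) next
    m0 <- env$mnm_null_mle(x[1], x[2], y[1], y[2], a[1], a[2], b[1], b[2])
    f0 <- function(m) oracle_loglik(c(x, y), c(a * m, b * (1 - m)))
    opt <- stats::optimize(f0, c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-10)
    expect_equal(m0, opt$maximum, tolerance = 1e-4)
  }
})

test_that("the statistic is a true likelihood ratio: non-negative and at the optimum", {
  set.seed(83)
  env <- asNamespace("medipmre")
  for (i in 1:40) {
    a <- runif(2, 0.5, 25); b <- runif(2, 0.5, 25)
    x <- rpois(2, 6); y <- rpois(2, 4)
    if (sum(x) + sum(y) == 0) next
    st <- env$mnm_statistic(x[1], x[2], y[1], y[2], a[1], a[2], b[1], b[2])
    expect_gte(st, 0)
    expect_equal(st, oracle_statistic(x[1], x[2], y[1], y[2],
                                      a[1], a[2], b[1], b[2]),
                 tolerance = 1e-5)
  }
})

test_that("BH q-values behave like the step-up procedure", {
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(84)
  p <- runif(500)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("DMR calls threshold q-values and merge same-direction runs", {
  res <- data.frame(chrom = "chr1",
                    start = c(0, 500, 1000, 1500, 2500),
                    end = c(500, 1000, 1500, 2000, 3000),
                    tested = TRUE, m1_hat = 0.2, m2_hat = 0.8,
                    statistic = 10,
                    p_value = c(1e-5, 1e-5, 1e-5, 0.5, 1e-5),
                    direction = c("group2-higher", "group2-higher",
                                  "group1-higher", "group2-higher",
                                  "group2-higher"),
                    q_value = c(1e-4, 1e-4, 1e-4, 0.6, 1e-4))
  plain <- call_dmrs(res)
  expect_equal(nrow(plain$dmrs), 4)
  expect_equal(plain$summary$total, 4)

  merged <- call_dmrs(res, merge_adjacent = TRUE)
  # bins 1-2 merge (touching, same direction); bin 3 touches but differs in
  # direction; bin 5 is separated by a non-significant gap
  expect_equal(nrow(merged$dmrs), 3)
  expect_equal(merged$dmrs$end[1] - merged$dmrs$start[1], 1000)

  none <- call_dmrs(transform(res, q_value = 0.9))
  expect_equal(none$summary$total, 0)
  expect_equal(none$summary$pct_group1, 0)
})

test_that("methylation estimates recover the truth at high depth", {
  sim <- null_count_table(1500, depth = 500, seed = 85,
                          dmr_frac = 0.2, delta = 0.4)
  res <- mnm_test_all(sim$counts)
  keep <- res$tested & !is.na(res$m1_hat) & !is.na(res$m2_hat)
  err <- c(abs(res$m1_hat[keep] - sim$truth$m[keep, 1]),
           abs(res$m2_hat[keep] - sim$truth$m[keep, 2]))
  expect_lt(mean(err), 0.05)
})

test_that("direction of planted changes is recovered and label-swap flips it", {
  sim <- null_count_table(2000, depth = 60, seed = 86,
                          dmr_frac = 0.1, delta = 0.5)
  res <- mnm_test_all(sim$counts)
  hit <- intersect(sim$truth$dmr_bins,
                   which(res$tested & !is.na(res$q_value) & res$q_value < 0.05))
  expect_gt(length(hit), 0)
  planted <- sim$truth$dmr_direction[match(hit, sim$truth$dmr_bins)]
  expect_identical(res$direction[hit], planted)

  swapped <- sim$counts
  names(swapped)[match(c("medip_1", "medip_2", "mre_1", "mre_2"), names(swapped))] <-
    c("medip_2", "medip_1", "mre_2", "mre_1")
  res2 <- mnm_test_all(swapped)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-9)
  flip <- c("group1-higher" = "group2-higher", "group2-higher" = "group1-higher",
            none = "none")
  expect_identical(unname(flip[res$direction]), res2$direction)
})
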