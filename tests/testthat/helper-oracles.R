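# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's internal code paths: plain loops, stats::optim /
# stats::optimize, stats::dmultinom.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# sliding-window substring scan (no regex, no Biostrings)
oracle_count_occurrences <- function(seq, pattern) {
  n <- 0L
  w <- nchar(pattern)
  if (nchar(seq) < w) return(0L)
  for (i in seq_len(nchar(seq) - w + 1L))
    if (substr(seq, i, i + w - 1L) == pattern) n <- n + 1L
  n
}

# per-base interval membership count
oracle_assign_reads <- function(anchors_chrom, anchors_pos, bins) {
  counts <- integer(length(bins))
  dropped <- 0L
  for (r in seq_along(anchors_pos)) {
    hit <- which(as.character(seqnames(bins)) == anchors_chrom[r] &
                 start(bins) <= anchors_pos[r] & end(bins) >= anchors_pos[r])
    if (length(hit)) counts[hit[1]] <- counts[hit[1]] + 1L else dropped <- dropped + 1L
  }
  list(counts = counts, dropped = dropped)
}

# textbook step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# conditional-multinomial log-likelihood, written independently
oracle_loglik <- function(n, u) {
  sum(ifelse(n > 0, n * log(u), 0)) - sum(n) * log(sum(u))
}

oracle_statistic <- function(x1, x2, y1, y2, a1, a2, b1, b2) {
  n <- c(x1, x2, y1, y2)
  f_alt <- function(p) -oracle_loglik(n, c(a1 * p[1], a2 * p[2],
                                           b1 * (1 - p[1]), b2 * (1 - p[2])))
  best <- Inf
  for (st in list(c(0.5, 0.5), c(0.2, 0.8), c(0.8, 0.2), c(0.05, 0.95))) {
    o <- stats::optim(st, f_alt, method = "L-BFGS-B",
                      lower = 1e-9, upper = 1 - 1e-9,
                      control = list(factr = 1e3))
    best <- min(best, o$value)
  }
  f0 <- function(m) oracle_loglik(n, c(a1 * m, a2 * m, b1 * (1 - m), b2 * (1 - m)))
  o0 <- stats::optimize(f0, c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-12)
  max(0, 2 * (-best - o0$objective))
}

# exact conditional p by full enumeration with dmultinom
oracle_exact_p <- function(x1, x2, y1, y2, a1, a2, b1, b2) {
  tot <- x1 + x2 + y1 + y2
  f0 <- function(m) oracle_loglik(c(x1, x2, y1, y2),
                                  c(a1 * m, a2 * m, b1 * (1 - m), b2 * (1 - m)))
  m0 <- stats::optimize(f0, c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-12)$maximum
  u <- c(a1 * m0, a2 * m0, b1 * (1 - m0), b2 * (1 - m0))
  pr <- u / sum(u)
  s_obs <- oracle_statistic(x1, x2, y1, y2, a1, a2, b1, b2)
  p <- 0
  for (i in 0:tot) for (j in 0:(tot - i)) for (k in 0:(tot - i - j)) {
    l <- tot - i - j - k
    s <- oracle_statistic(i, j, k, l, a1, a2, b1, b2)
    if (s >= s_obs - 1e-6)
      p <- p + stats::dmultinom(c(i, j, k, l), prob = pr)
  }
  p
}

# draw a random bin under the depth-30 two-sample study conditions,
# conditioned on the bin total falling inside [lo, hi]
draw_study_bin <- function(lo = 30, hi = 100, base_m = 0.5, depth = 30) {
  km <- depth / (9 * base_m)
  kr <- depth / (5 * (1 - base_m))
  repeat {
    cb <- max(1, rpois(1, 9)); rb <- max(1, rpois(1, 5))
    sm <- runif(2, 1.0, 1.3); sr <- runif(2, 1.0, 1.3)
    a <- km * cb * sm; b <- kr * rb * sr
    x <- rpois(2, a * base_m); y <- rpois(2, b * (1 - base_m))
    tot <- sum(x) + sum(y)
    if (tot >= lo && tot <= hi) {
      return(list(x = x, y = y, a = a, b = b, cb = cb, rb = rb, tot = tot))
    }
  }
}

# synthetic null count table without sequence (content drawn as in the
# genome generator), for calibration experiments
null_count_table <- function(n_bins, depth = 30, base_m = 0.5, seed = 1,
                             dmr_frac = 0, delta = 0.5) {
  set.seed(seed)
  cb <- pmax(1, rpois(n_bins, 9))
  rb <- pmax(1, rpois(n_bins, 5))
  meth <- gen_methylome(n_bins, dmr_frac, delta, base_m, seed = seed + 1)
  counts <- gen_counts(meth$m, cb, rb, mean_depth = depth, seed = seed + 2)
  counts <- cbind(data.frame(chrom = "chr1",
                             start = (seq_len(n_bins) - 1L) * 500L,
                             end = seq_len(n_bins) * 500L), counts)
  list(counts = counts, truth = meth)
}
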