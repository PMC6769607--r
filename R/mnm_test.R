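#' Library-size factors per sample and assay
#'
#' For each assay (MeDIP, MRE) the factor of a sample is its total mapped
#' count divided by the across-sample mean of totals, so factors average 1
#' within an assay and dividing raw counts by them equalises expected
#' genome-wide totals. A between-assay scale is also computed (mean total
#' over summed bin content), which calibrates MeDIP against MRE rates under
#' the model; it cancels from the test statistic but anchors the reported
#' methylation estimates.
#'
#' @param counts Count table from [bin_count_table()] (or read via
#'   [read_count_table()]).
#' @return List with numeric vectors `medip` and `mre` (per-sample factors)
#'   and `assay_scale` (per-assay calibration constants).
#' @export
size_factors <- function(counts) {
  out <- list()
  for (assay in c("medip", "mre")) {
    mat <- count_table_assay(counts, assay)
    totals <- colSums(mat)
    if (any(totals == 0))
      stopf("sample(s) %s have zero total %s counts",
            paste(colnames(mat)[totals == 0], collapse = ", "), assay)
    out[[assay]] <- as.numeric(totals / mean(totals))
    content <- if (assay == "medip") counts$cpg else counts$mre_sites
    out$assay_scale[assay] <- mean(totals) / sum(content)
  }
  out
}

# --- conditional multinomial likelihood machinery (vectorised) -------------
#
# Cells (x1, x2, y1, y2) with rates proportional to
#   (a1 m1, a2 m2, b1 (1 - m1), b2 (1 - m2)).
# Conditional on the total T the counts are multinomial; the common scale
# kappa cancels.

# recycle scalar arguments against vector ones (base ifelse() does not)
mnm_recycle <- function(env) {
  vars <- c("x1", "x2", "y1", "y2", "a1", "a2", "b1", "b2")
  vars <- vars[vars %in% ls(env)]
  k <- max(vapply(vars, function(v) length(get(v, env)), integer(1)))
  for (v in vars) assign(v, rep_len(get(v, env), k), env)
  invisible(k)
}

mnm_loglik <- function(x1, x2, y1, y2, a1, a2, b1, b2, m1, m2) {
  mnm_recycle(environment())
  u <- cbind(a1 * m1, a2 * m2, b1 * (1 - m1), b2 * (1 - m2))
  n <- cbind(x1, x2, y1, y2)
  tot <- x1 + x2 + y1 + y2
  rowSums(ifelse(n > 0, n * log(u), 0)) -
    ifelse(tot > 0, tot * log(rowSums(u)), 0)
}

# Root in [0,1] of the per-group stationarity condition
#   x/m - y/(1-m) = q   (q = G (a - b), G = T/S)
# which is the quadratic q m^2 - (x+y+q) m + x = 0. For x,y > 0 the score is
# strictly decreasing in m so the root is unique; boundary cells are handled
# explicitly.
mnm_group_root <- function(x, y, q, a, b) {
  k <- max(length(x), length(y), length(q), length(a), length(b))
  x <- rep_len(x, k); y <- rep_len(y, k); q <- rep_len(q, k)
  a <- rep_len(a, k); b <- rep_len(b, k)
  s <- x + y + q
  disc <- pmax(s^2 - 4 * q * x, 0)
  r <- ifelse(x > 0 & y > 0,
              ifelse(abs(q) < 1e-12, x / (x + y), 2 * x / (s + sqrt(disc))),
       ifelse(x == 0 & y > 0, ifelse(q < -y, 1 + y / q, 0),
       ifelse(y == 0 & x > 0, ifelse(q > x, x / q, 1),
       ifelse(a > b, 0, ifelse(a < b, 1, 0.5)))))
  pmin(pmax(r, 0), 1)
}

# Joint MLE (m1, m2) of the 4-cell conditional multinomial, by fixed-point
# iteration on the normalizer; initialised at the per-group ratio estimates.
mnm_alt_mle <- function(x1, x2, y1, y2, a1, a2, b1, b2,
                        max_iter = 500, tol = 1e-13) {
  mnm_recycle(environment())
  m1 <- mnm_ratio_estimate(x1, y1, a1, b1)
  m2 <- mnm_ratio_estimate(x2, y2, a2, b2)
  m1 <- ifelse(is.na(m1), ifelse(a1 > b1, 0, 1), m1)
  m2 <- ifelse(is.na(m2), ifelse(a2 > b2, 0, 1), m2)
  tot <- x1 + x2 + y1 + y2
  for (it in seq_len(max_iter)) {
    S <- a1 * m1 + b1 * (1 - m1) + a2 * m2 + b2 * (1 - m2)
    G <- tot / S
    n1 <- mnm_group_root(x1, y1, G * (a1 - b1), a1, b1)
    n2 <- mnm_group_root(x2, y2, G * (a2 - b2), a2, b2)
    d <- max(abs(n1 - m1), abs(n2 - m2), na.rm = TRUE)
    m1 <- n1; m2 <- n2
    if (d < tol) break
  }
  list(m1 = m1, m2 = m2)
}

# Null MLE of the common m. The score equation collapses to a linear one
# with closed-form solution m0 = (X/A) / (X/A + Y/B), the pooled ratio
# estimate (equivalently the maximiser found by bounded 1-D optimisation).
# Assays with zero site content (A or B zero, forcing zero counts) drop out.
mnm_null_mle <- function(x1, x2, y1, y2, a1, a2, b1, b2) {
  mnm_recycle(environment())
  X <- x1 + x2; Y <- y1 + y2; A <- a1 + a2; B <- b1 + b2
  Xa <- ifelse(A > 0, X / A, 0)
  Yb <- ifelse(B > 0, Y / B, 0)
  ifelse(Xa + Yb > 0, Xa / (Xa + Yb), 0.5)
}

# per-group normalised-read ratio estimate (X/a) / (X/a + Y/b); NA when the
# group has no reads, boundary values when one assay is empty
mnm_ratio_estimate <- function(x, y, a, b) {
  k <- max(length(x), length(y), length(a), length(b))
  x <- rep_len(x, k); y <- rep_len(y, k)
  a <- rep_len(a, k); b <- rep_len(b, k)
  xa <- ifelse(a > 0, x / a, 0)
  yb <- ifelse(b > 0, y / b, 0)
  ifelse(xa + yb > 0, xa / (xa + yb), NA_real_)
}

# Likelihood-ratio statistic; >= 0 up to round-off, clamped.
mnm_statistic <- function(x1, x2, y1, y2, a1, a2, b1, b2) {
  alt <- mnm_alt_mle(x1, x2, y1, y2, a1, a2, b1, b2)
  m0 <- mnm_null_mle(x1, x2, y1, y2, a1, a2, b1, b2)
  s <- 2 * (mnm_loglik(x1, x2, y1, y2, a1, a2, b1, b2, alt$m1, alt$m2) -
            mnm_loglik(x1, x2, y1, y2, a1, a2, b1, b2, m0, m0))
  pmax(s, 0)
}

# all compositions of tot into 4 non-negative cells
mnm_enumerate_outcomes <- function(tot) {
  g <- expand.grid(x1 = 0:tot, x2 = 0:tot, y1 = 0:tot,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$x1 + g$x2 + g$y1 <= tot, , drop = FALSE]
  g$y2 <- tot - g$x1 - g$x2 - g$y1
  g
}

# Exact conditional p: total probability (under the null multinomial at the
# observed-data m0) of outcomes whose statistic reaches the observed one.
mnm_exact_p <- function(tot, a1, a2, b1, b2, m0, stat_obs) {
  g <- mnm_enumerate_outcomes(tot)
  u <- c(a1 * m0, a2 * m0, b1 * (1 - m0), b2 * (1 - m0))
  pr <- u / sum(u)
  nmat <- as.matrix(g)
  lpr <- ifelse(pr > 0, log(pr), -Inf)
  cell <- sweep(nmat, 2, lpr, function(n, l) ifelse(n > 0, n * l, 0))
  lp <- lgamma(tot + 1) - rowSums(lgamma(nmat + 1)) + rowSums(cell)
  # outcomes with a count in a zero-probability cell cannot occur under the
  # null; drop them before evaluating statistics
  keep <- is.finite(lp)
  g <- g[keep, , drop = FALSE]; lp <- lp[keep]
  st <- mnm_statistic(g$x1, g$x2, g$y1, g$y2, a1, a2, b1, b2)
  sum(exp(lp)[st >= stat_obs - 1e-9])
}

#' Per-bin integrative MeDIP/MRE methylation test (all bins)
#'
#' Tests, for every bin, the null hypothesis that the latent methylation
#' level is equal in the two samples. MeDIP counts `X_i` and MRE counts
#' `Y_i` are modelled as independent Poisson variables with rates
#' `kappa a_i m_i` and `kappa b_i (1 - m_i)`, where `a_i` scales with the
#' bin's CpG count and the sample's MeDIP size factor, and `b_i` with the
#' MRE-site count and MRE size factor. Conditional on the bin total
#' `T = X1 + X2 + Y1 + Y2` the four counts are multinomial and `kappa`
#' cancels; the statistic is twice the log-likelihood ratio between the
#' two-parameter fit and the common-methylation fit (common `m` estimated by
#' 1-D maximum likelihood, available in closed form). The p-value comes from
#' the chi-square distribution with 1 df when `T > exact_threshold`,
#' otherwise from exact enumeration of the conditional multinomial.
#'
#' Reported per-sample methylation estimates are the normalised-read ratio
#' estimates `(X_i/a_i) / (X_i/a_i + Y_i/b_i)`; the direction of change is
#' the sign of their difference. Bins with no CpG and no MRE site are not
#' tested, nor are bins whose content contradicts their counts (reads in an
#' assay whose site content is zero).
#'
#' @param counts Count table from [bin_count_table()] with exactly two
#'   sample columns per assay.
#' @param factors Size factors from [size_factors()]; computed from `counts`
#'   when omitted.
#' @param exact_threshold Largest bin total handled by exact enumeration
#'   (default 20); enumeration cost grows cubically with the total.
#' @return A `data.frame` (one row per bin): `chrom`, `start`, `end`,
#'   `tested`, `m1_hat`, `m2_hat`, `statistic`, `p_value`, `direction`
#'   (`"group1-higher"`, `"group2-higher"` or `"none"`), and `q_value`
#'   (Benjamini-Hochberg across tested bins).
#' @seealso [mnm_test()] for a single bin, [call_dmrs()] for significance
#'   calls.
#' @export
mnm_test_all <- function(counts, factors = NULL, exact_threshold = 20) {
  medip <- count_table_assay(counts, "medip")
  mre <- count_table_assay(counts, "mre")
  if (ncol(medip) != 2L)
    stopf("the test compares exactly two samples, got %d", ncol(medip))
  if (any(medip < 0) || any(mre < 0)) stopf("negative read counts")
  factors <- factors %||% size_factors(counts)
  cb <- counts$cpg; rb <- counts$mre_sites
  x1 <- medip[, 1]; x2 <- medip[, 2]; y1 <- mre[, 1]; y2 <- mre[, 2]

  a1 <- factors$assay_scale["medip"] * cb * factors$medip[1]
  a2 <- factors$assay_scale["medip"] * cb * factors$medip[2]
  b1 <- factors$assay_scale["mre"] * rb * factors$mre[1]
  b2 <- factors$assay_scale["mre"] * rb * factors$mre[2]

  tested <- (cb > 0 | rb > 0) &
    !(cb == 0 & (x1 > 0 | x2 > 0)) &
    !(rb == 0 & (y1 > 0 | y2 > 0))
  tot <- x1 + x2 + y1 + y2

  n <- nrow(counts)
  stat <- rep(NA_real_, n); p <- rep(NA_real_, n)
  m1h <- rep(NA_real_, n); m2h <- rep(NA_real_, n)
  dir <- rep("none", n)

  idx <- which(tested & tot > 0)
  if (length(idx)) {
    i <- idx
    m1h[i] <- mnm_ratio_estimate(x1[i], y1[i], a1[i], b1[i])
    m2h[i] <- mnm_ratio_estimate(x2[i], y2[i], a2[i], b2[i])
    stat[i] <- mnm_statistic(x1[i], x2[i], y1[i], y2[i],
                             a1[i], a2[i], b1[i], b2[i])
    asym <- i[tot[i] > exact_threshold]
    p[asym] <- pchisq(stat[asym], df = 1, lower.tail = FALSE)
    for (j in i[tot[i] <= exact_threshold]) {
      m0 <- mnm_null_mle(x1[j], x2[j], y1[j], y2[j], a1[j], a2[j], b1[j], b2[j])
      p[j] <- min(1, mnm_exact_p(tot[j], a1[j], a2[j], b1[j], b2[j], m0, stat[j]))
    }
    ok <- !is.na(m1h[i]) & !is.na(m2h[i])
    dir[i[ok]] <- ifelse(m1h[i[ok]] > m2h[i[ok]], "group1-higher",
                  ifelse(m2h[i[ok]] > m1h[i[ok]], "group2-higher", "none"))
  }
  # informative but read-free bins: tested, no evidence
  zero <- which(tested & tot == 0)
  stat[zero] <- 0; p[zero] <- 1

  res <- data.frame(chrom = counts$chrom, start = counts$start,
                    end = counts$end, tested = tested,
                    m1_hat = m1h, m2_hat = m2h, statistic = stat,
                    p_value = p, direction = dir, stringsAsFactors = FALSE)
  res$q_value <- NA_real_
  res$q_value[res$tested] <- bh_fdr(res$p_value[res$tested])
  res
}

#' Integrative methylation test for a single bin
#'
#' Single-bin interface to the test described in [mnm_test_all()].
#'
#' @param cpg,mre_sites Bin CpG and MRE-site content.
#' @param medip,mre Length-2 integer vectors of per-sample read counts.
#' @param factors Size factors (see [size_factors()]); defaults to unit
#'   factors and unit assay scale.
#' @inheritParams mnm_test_all
#' @return One-row `data.frame` as in [mnm_test_all()] (without `q_value`).
#' @examples
#' mnm_test(cpg = 5, mre_sites = 5, medip = c(10, 10), mre = c(5, 5))
#' @export
mnm_test <- function(cpg, mre_sites, medip, mre, factors = NULL,
                     exact_threshold = 20) {
  stopifnot(length(medip) == 2L, length(mre) == 2L)
  factors <- factors %||%
    list(medip = c(1, 1), mre = c(1, 1), assay_scale = c(medip = 1, mre = 1))
  counts <- data.frame(chrom = "bin", start = 0L, end = 1L,
                       cpg = cpg, mre_sites = mre_sites,
                       medip_1 = medip[1], medip_2 = medip[2],
                       mre_1 = mre[1], mre_2 = mre[2])
  res <- mnm_test_all(counts, factors = factors,
                      exact_threshold = exact_threshold)
  res$q_value <- NULL
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' input order is preserved. Backed by [stats::p.adjust()] after validating
#' that every p-value lies in (0, 1].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stopf("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Call differentially methylated regions
#'
#' A DMR is a tested bin with q-value below `alpha`. With
#' `merge_adjacent = TRUE`, touching significant bins with the same
#' direction are merged into a single region (multi-bin DMRs); the default
#' keeps single bins as reported regions.
#'
#' @param results Output of [mnm_test_all()].
#' @param alpha FDR threshold (default 0.05).
#' @param merge_adjacent Merge touching same-direction significant bins.
#' @return List with `dmrs` (a `data.frame`: `chrom`, `start`, `end`,
#'   `direction`, `q_value` — minimum q over merged bins) and `summary`
#'   (total and per-direction counts with percentages rounded half-up to
#'   one decimal).
#' @export
call_dmrs <- function(results, alpha = 0.05, merge_adjacent = FALSE) {
  sig <- results[results$tested & !is.na(results$q_value) &
                 results$q_value < alpha, , drop = FALSE]
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  if (nrow(sig) && merge_adjacent) {
    new_run <- c(TRUE, !(sig$chrom[-1] == sig$chrom[-nrow(sig)] &
                         sig$start[-1] == sig$end[-nrow(sig)] &
                         sig$direction[-1] == sig$direction[-nrow(sig)]))
    run <- cumsum(new_run)
    sig <- do.call(rbind, lapply(split(sig, run), function(d)
      data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
                 direction = d$direction[1], q_value = min(d$q_value),
                 stringsAsFactors = FALSE)))
    rownames(sig) <- NULL
  } else {
    sig <- sig[, c("chrom", "start", "end", "direction", "q_value")]
    rownames(sig) <- NULL
  }
  list(dmrs = sig, summary = dmr_direction_summary(
    n_group1 = sum(sig$direction == "group1-higher"),
    n_group2 = sum(sig$direction == "group2-higher"),
    n_none = sum(sig$direction == "none")))
}

#' Direction summary of a DMR set
#'
#' Totals and per-direction percentages (rounded half-up to one decimal)
#' from per-direction counts; used both by [call_dmrs()] and to reproduce
#' printed summaries from published counts.
#'
#' @param n_group1,n_group2 Counts of DMRs more methylated in group 1 / 2.
#' @param n_none Count of significant regions without a direction (possible
#'   only for bins with single-assay information).
#' @return List with `total`, `n_group1`, `n_group2`, `pct_group1`,
#'   `pct_group2`.
#' @examples
#' dmr_direction_summary(534, 885)
#' @export
dmr_direction_summary <- function(n_group1, n_group2, n_none = 0) {
  total <- n_group1 + n_group2 + n_none
  list(total = total, n_group1 = n_group1, n_group2 = n_group2,
       pct_group1 = if (total > 0) round_half_up(100 * n_group1 / total) else 0,
       pct_group2 = if (total > 0) round_half_up(100 * n_group2 / total) else 0)
}
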