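#' Percent methylation from MSP quantities
#'
#' `100 * M / (M + U)` for methylated and unmethylated template quantities
#' from methylation-specific PCR. Vectorised.
#'
#' @param M,U Non-negative quantities, not both zero.
#' @return Percentage in `[0, 100]`.
#' @examples
#' percent_methylated(3, 1)
#' @export
percent_methylated <- function(M, U) {
  if (any(M < 0) || any(U < 0)) stopf("quantities must be non-negative")
  if (any(M + U == 0)) stopf("M + U must be positive")
  100 * M / (M + U)
}

#' Relative expression normalised to housekeeping genes
#'
#' Target quantity divided by the geometric mean of the housekeeping
#' quantities (conventionally three, e.g. Actb/Gapdh/Rpl7a).
#'
#' @param target Positive target-gene quantity (vectorised).
#' @param housekeeping Numeric vector (or matrix with one row per target
#'   value) of positive housekeeping quantities.
#' @return Relative expression.
#' @examples
#' normalize_expression(4, c(2, 4, 8))
#' @export
normalize_expression <- function(target, housekeeping) {
  hk <- if (is.matrix(housekeeping)) housekeeping else
    matrix(housekeeping, nrow = length(target), ncol = length(housekeeping),
           byrow = TRUE)
  if (any(hk <= 0)) stopf("housekeeping quantities must be positive")
  target / exp(rowMeans(log(hk)))
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' `100 * (10^(-1/slope) - 1)`; a slope of `-1/log10(2)` (perfect doubling)
#' gives 100%. Slopes between -3.6 and -3.1 correspond to the conventional
#' 90-110% acceptability band.
#'
#' @param slope Negative standard-curve slope (Ct versus log10 input).
#' @return Efficiency in percent.
#' @examples
#' qpcr_efficiency(-1 / log10(2))
#' @export
qpcr_efficiency <- function(slope) {
  if (any(slope >= 0)) stopf("standard-curve slope must be negative")
  100 * (10^(-1 / slope) - 1)
}

#' Two-tailed two-sample t-test
#'
#' Welch's unequal-variance test by default; set `var_equal = TRUE` for the
#' pooled-variance variant.
#'
#' @param group_a,group_b Numeric vectors, each with at least two values;
#'   at least one group must have nonzero variance.
#' @param var_equal Pool variances (default `FALSE`).
#' @return List with `t` and `p`.
#' @export
two_tailed_t <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("each group needs at least two values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stopf("both groups have zero variance")
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Per-site and averaged MSP group comparisons
#'
#' For each CpG site, percent methylation per animal is compared between
#' groups with a two-tailed t-test; additionally each animal's percentages
#' are averaged across sites and the averages compared (the per-site versus
#' region-average pattern used in MSP validation).
#'
#' @param msp Data frame as produced by [gen_validation_data()]: `site`,
#'   `animal`, `group`, `methylated_quantity`, `unmethylated_quantity`.
#' @param var_equal Pool variances (default `FALSE`, Welch).
#' @return List with `per_site` (`data.frame`: `site`, mean percentage per
#'   group, `t`, `p`) and `average` (list with group means, `t`, `p`).
#' @export
msp_group_tests <- function(msp, var_equal = FALSE) {
  msp$pct <- percent_methylated(msp$methylated_quantity,
                                msp$unmethylated_quantity)
  per_site <- do.call(rbind, lapply(split(msp, msp$site), function(d) {
    a <- d$pct[d$group == "group1"]; b <- d$pct[d$group == "group2"]
    ht <- two_tailed_t(a, b, var_equal)
    data.frame(site = d$site[1], mean_group1 = mean(a), mean_group2 = mean(b),
               t = ht$t, p = ht$p, stringsAsFactors = FALSE)
  }))
  rownames(per_site) <- NULL
  avg <- stats::aggregate(pct ~ animal + group, msp, mean)
  a <- avg$pct[avg$group == "group1"]; b <- avg$pct[avg$group == "group2"]
  ht <- two_tailed_t(a, b, var_equal)
  list(per_site = per_site,
       average = list(mean_group1 = mean(a), mean_group2 = mean(b),
                      t = ht$t, p = ht$p))
}

#' Per-gene expression comparisons
#'
#' Normalises each measurement to the geometric mean of its housekeeping
#' quantities and compares groups per gene with a two-tailed t-test.
#'
#' @param expression Data frame as produced by [gen_validation_data()]:
#'   `gene`, `animal`, `group`, `target`, `hk1`-`hk3`.
#' @param var_equal Pool variances (default `FALSE`).
#' @return `data.frame`: `gene`, mean relative expression per group, `t`,
#'   `p`.
#' @export
expression_group_tests <- function(expression, var_equal = FALSE) {
  hk <- as.matrix(expression[, grep("^hk", colnames(expression)), drop = FALSE])
  expression$rel <- normalize_expression(expression$target, hk)
  out <- do.call(rbind, lapply(split(expression, expression$gene), function(d) {
    a <- d$rel[d$group == "group1"]; b <- d$rel[d$group == "group2"]
    ht <- two_tailed_t(a, b, var_equal)
    data.frame(gene = d$gene[1], mean_group1 = mean(a), mean_group2 = mean(b),
               t = ht$t, p = ht$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
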