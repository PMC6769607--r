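#' Hypergeometric term enrichment with reporting filters
#'
#' For each gene set the upper-tail hypergeometric probability of observing
#' at least the seen number of query genes is computed, q-values are
#' obtained by Benjamini-Hochberg across all tested terms, and the reported
#' list is filtered to terms with at least `min_count` query genes and a
#' fold enrichment (query proportion over background proportion) of at
#' least `min_fold`.
#'
#' @param query_genes Character vector of genes of interest (e.g.
#'   differentially methylated genes); must be a subset of
#'   `background_genes`.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); sets are intersected with the background.
#' @param background_genes Universe of genes (defaults to the union of all
#'   gene sets).
#' @param min_count,min_fold Reporting filters (defaults 2 and 1.5).
#' @return `data.frame` sorted by p-value: `term`, `dmg_count`,
#'   `term_size`, `query_size`, `background_size`, `fold_enrichment`,
#'   `p_value`, `q_value`, plus a list-column `members` with the query
#'   genes in the term. The unfiltered table is attached as attribute
#'   `"all_terms"`.
#' @export
enrich_terms <- function(query_genes, gene_sets, background_genes = NULL,
                         min_count = 2, min_fold = 1.5) {
  background_genes <- unique(background_genes %||% unlist(gene_sets))
  query_genes <- unique(query_genes)
  missing <- setdiff(query_genes, background_genes)
  if (length(missing))
    stopf("query gene(s) absent from background: %s",
          paste(missing, collapse = ", "))
  N <- length(background_genes)
  n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], background_genes)
    K <- length(set)
    if (K == 0) return(NULL)
    members <- intersect(query_genes, set)
    k <- length(members)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, dmg_count = k, term_size = K, query_size = n,
               background_size = N,
               fold_enrichment = if (n > 0) (k / n) / (K / N) else 0,
               p_value = p, members = I(list(members)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(structure(data.frame(), all_terms = data.frame()))
  res$q_value <- bh_fdr(res$p_value)
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  keep <- res[res$dmg_count >= min_count &
              res$fold_enrichment >= min_fold, , drop = FALSE]
  rownames(keep) <- NULL
  structure(keep, all_terms = res)
}

cohen_kappa <- function(a, b) {
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Cluster enriched terms by gene-membership agreement
#'
#' Terms are linked when the Cohen's kappa of their query-gene membership
#' vectors reaches `kappa_threshold`; clusters are the connected components
#' of that graph. A cluster is reported only if it has at least two terms
#' and the majority of its terms are FDR-significant at `alpha`. The
#' enrichment score is `-log10` of the geometric mean of the member
#' p-values.
#'
#' @param results Output of [enrich_terms()] (needs the `members`
#'   list-column).
#' @param kappa_threshold Linkage threshold on kappa (default 0.5).
#' @param alpha FDR level used by the majority rule (default 0.05).
#' @return `data.frame` sorted by decreasing score: `cluster`, `n_terms`,
#'   `enrichment_score`, and a list-column `terms`.
#' @export
cluster_terms <- function(results, kappa_threshold = 0.5, alpha = 0.05) {
  empty <- data.frame(cluster = integer(), n_terms = integer(),
                      enrichment_score = numeric(), terms = I(list()))
  if (nrow(results) < 2) return(empty)
  universe <- unique(unlist(results$members))
  if (!length(universe)) return(empty)
  memb <- vapply(results$members, function(m) universe %in% m,
                 logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe))
  nt <- nrow(results)
  edges <- NULL
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    if (cohen_kappa(memb[, i], memb[, j]) >= kappa_threshold)
      edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(n = nt, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  out <- lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    if (length(idx) < 2) return(NULL)
    qs <- results$q_value[idx]
    if (mean(qs < alpha) <= 0.5) return(NULL)
    data.frame(cluster = cid, n_terms = length(idx),
               enrichment_score = mean(-log10(results$p_value[idx])),
               terms = I(list(results$term[idx])), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(-out$enrichment_score), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
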