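# Gene-set over-representation of DMC-associated genes by Fisher's exact
# test (one-sided, hypergeometric tail), BH-adjusted across terms.

#' Fisher's exact gene-set over-representation test
#'
#' For each gene set, forms the 2x2 table of query/background membership
#' (k query genes in the term, n-k outside; K-k background-only genes in
#' the term, N-n-K+k outside) and computes the one-sided over-representation
#' p-value, which equals the hypergeometric upper tail at k. Gene sets are
#' intersected with the background universe first; q-values are BH over all
#' tested terms. The recommended background is the set of nearest genes of
#' all tested CpGs (RRBS coverage is non-uniform, so a whole-genome
#' background would overstate enrichment); the recommended query is the
#' union of nearest genes of significant DMCs and of their correlating
#' genes.
#'
#' @param query character vector of query gene ids (subset of background;
#'   genes outside the background are dropped with a warning).
#' @param background character vector: the gene universe.
#' @param gene_sets named list of character vectors (e.g. from [readGmt()]).
#' @param fdr_threshold FDR threshold for the `enriched` flag
#'   (default 0.05).
#' @return data.frame sorted by p-value with columns `term`, `k`, `K`, `n`,
#'   `N`, `odds_ratio` (conditional MLE), `p_value`, `q_value`, `enriched`.
#' @export
fisherEnrichment <- function(query, background, gene_sets,
                             fdr_threshold = 0.05) {
  background <- unique(background)
  if (!length(background)) stop("empty background universe")
  query <- unique(query)
  extra <- setdiff(query, background)
  if (length(extra)) {
    warning(length(extra), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), background)
    K <- length(set)
    k <- length(intersect(set, query))
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), 2, 2)
    ft <- fisher.test(tab, alternative = "greater")
    data.frame(term = term, k = k, K = K, n = n, N = N,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out$enriched <- out$q_value < fdr_threshold
  out[order(out$p_value, out$term), , drop = FALSE]
}
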