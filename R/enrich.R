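## Hypergeometric GO-term over-representation with FDR control valid
## under dependency (Benjamini-Yekutieli by default).

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` carry the term. Computed through
#' `stats::phyper`, which works in log space internally; exact to machine
#' precision.
#'
#' @param N universe size.
#' @param K genes in the universe carrying the term.
#' @param n list size.
#' @param k genes in the list carrying the term.
#' @return the tail probability.
#' @examples
#' hypergeomUpper(10, 5, 3, 3)  # choose(5,3)/choose(10,3) = 1/12
#' @export
hypergeomUpper <- function(N, K, n, k) {
  N <- .checkCount(N, "N"); K <- .checkCount(K, "K", min = 0L)
  n <- .checkCount(n, "n", min = 0L); k <- .checkCount(k, "k", min = 0L)
  if (k > n || n > N || K > N || k > K)
    .stopf("inconsistent counts: need k <= min(n, K), n <= N, K <= N")
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' GO-term enrichment of a gene list against a universe
#'
#' One hypergeometric upper-tail test per term with at least `min_hits`
#' hits in the list; adjustment over the tested family by
#' Benjamini-Yekutieli (valid under arbitrary dependency between terms,
#' the default) or Benjamini-Hochberg. Genes of the universe without any
#' annotation still count in the universe size `N` — they simply hit no
#' term. The enrichment ratio is the percentage of list genes with the
#' term over the percentage of universe genes with it.
#'
#' @param gene_list character vector, must be a subset of `universe`.
#' @param universe character vector of gene ids.
#' @param go_map data.frame with columns `gene_id`, `term` (flat map;
#'   supply an ancestor-expanded map if DAG propagation is wanted).
#' @param fdr `"BY"` (default) or `"BH"`.
#' @param min_hits minimum list hits for a term to enter the tested
#'   family (default 1; zero-hit terms are never tested).
#' @return `DataFrame` sorted by `p`, one row per tested term: `term`,
#'   `list_hits`, `list_size`, `universe_hits`, `universe_size`, `p`,
#'   `p_adjusted`, `ratio`.
#' @export
enrichTerms <- function(gene_list, universe, go_map,
                        fdr = c("BY", "BH"), min_hits = 1) {
  fdr <- match.arg(fdr)
  min_hits <- .checkCount(min_hits, "min_hits")
  gene_list <- unique(as.character(gene_list))
  universe <- unique(as.character(universe))
  if (!length(gene_list) || !length(universe))
    .stopf("gene_list and universe must be non-empty")
  extra <- setdiff(gene_list, universe)
  if (length(extra))
    .stopf("gene_list gene(s) not in universe: %s",
           paste(head(extra, 5), collapse = ", "))
  if (!all(c("gene_id", "term") %in% colnames(go_map)))
    .stopf("go_map needs columns gene_id, term")
  go_map <- unique(go_map[go_map$gene_id %in% universe,
                          c("gene_id", "term")])
  N <- length(universe)
  n <- length(gene_list)
  K_all <- table(go_map$term)
  in_list <- go_map$gene_id %in% gene_list
  k_all <- table(factor(go_map$term[in_list], levels = names(K_all)))
  keep <- k_all >= min_hits
  terms <- names(K_all)[keep]
  k <- as.integer(k_all[keep]); K <- as.integer(K_all[keep])
  p <- vapply(seq_along(terms),
              function(i) hypergeomUpper(N, K[i], n, k[i]), numeric(1))
  out <- S4Vectors::DataFrame(
    term = terms, list_hits = k, list_size = n,
    universe_hits = K, universe_size = N,
    p = p, p_adjusted = p.adjust(p, method = fdr),
    ratio = (k / n) / (K / N))
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  S4Vectors::metadata(out) <- list(fdr = fdr, min_hits = min_hits)
  out
}
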