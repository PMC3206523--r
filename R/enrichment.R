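#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of seeing at least
#' `k` annotated genes in a study set of size `n` drawn from a population
#' of `N` genes of which `K` carry the term.
#'
#' @param k study genes annotated to the term.
#' @param n study set size.
#' @param K population genes annotated to the term.
#' @param N population size.
#' @return p-value in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeom_upper_p <- function(k, n, K, N) {
  if (any(n > N) || any(K > N) || any(k < 0) || any(k > pmin(n, K)))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K), n <= N, K <= N")
  ifelse(k == 0, 1, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Hypergeometric GO-term enrichment of a study gene set
#'
#' Tests each term annotating at least one study gene for over-
#' representation against the population, with the raw-p cutoff
#' `p < alpha` (no multiple-testing correction, by design); Benjamini-
#' Hochberg q-values are emitted as an informational column only.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of background gene ids.
#' @param annotation data.frame (gene_id, go_id); annotations of genes
#'   outside the population are ignored. The input is taken as already
#'   propagated over the GO graph.
#' @param alpha raw-p enrichment cutoff (default 0.05, strict).
#' @return data.frame sorted by ascending p (ties by go_id): `go_id`, `k`,
#'   `n`, `K`, `N`, `p_value`, `q_value`, `enriched`.
#' @export
go_enrich <- function(study, population, annotation, alpha = 0.05) {
  study <- unique(study)
  population <- unique(population)
  if (!all(study %in% population))
    stop("study set must be a subset of the population")
  ann <- unique(annotation[annotation$gene_id %in% population,
                           c("gene_id", "go_id")])
  n <- length(study)
  N <- length(population)
  study_ann <- ann[ann$gene_id %in% study, , drop = FALSE]
  terms <- unique(study_ann$go_id)
  if (!length(terms))
    return(data.frame(go_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  k <- as.integer(table(factor(study_ann$go_id, levels = terms)))
  K <- as.integer(table(factor(ann$go_id[ann$go_id %in% terms],
                               levels = terms)))
  p <- hypergeom_upper_p(k, n, K, N)
  out <- data.frame(go_id = terms, k = k, n = n, K = K, N = N,
                    p_value = p, q_value = stats::p.adjust(p, "BH"),
                    enriched = p < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
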