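#' Bin percent identity into similarity classes
#'
#' Homolog pairs are classed by aligned-region identity: HS (high, > 90),
#' MS (moderate, 70-90], WS (weak, 45-70]; at or below 45% a pair is too
#' weak to call homologous and is binned `none` (excluded from replication
#' analysis). Boundaries go to the lower-similarity class, following the
#' strict ">" of the HS definition applied uniformly.
#'
#' @param pct_identity numeric vector in (0, 100].
#' @return character vector: "HS", "MS", "WS" or "none".
#' @examples
#' bin_similarity(c(92, 90, 70, 45)) # HS MS WS none
#' @export
bin_similarity <- function(pct_identity) {
  if (any(pct_identity <= 0 | pct_identity > 100))
    stop("percent identity must lie in (0, 100]")
  ifelse(pct_identity > 90, "HS",
         ifelse(pct_identity > 70, "MS",
                ifelse(pct_identity > 45, "WS", "none")))
}

# internal: keep only pairs informative for replication (identity > 45)
.informative_pairs <- function(homology) {
  homology[bin_similarity(homology$pct_identity) != "none", , drop = FALSE]
}

#' Genes of one list whose homologs replicate in the other
#'
#' Returns the members of `list_a` having at least one homolog (identity
#' > 45%) that belongs to `list_b`. Many-to-one homology is allowed; query
#' genes are counted, not pairs.
#'
#' @param list_a character vector of query-species gene ids.
#' @param homology data.frame (query, subject, pct_identity).
#' @param list_b character vector of subject-species gene ids.
#' @return the replicated subset of `list_a`.
#' @export
replicated_set <- function(list_a, homology, list_b) {
  if (!nrow(homology)) return(character(0))
  h <- .informative_pairs(homology)
  hits <- h$query[h$query %in% list_a & h$subject %in% list_b]
  list_a[list_a %in% hits]
}

# internal: swap query/subject columns
.invert_homology <- function(homology) {
  data.frame(query = homology$subject, subject = homology$query,
             pct_identity = homology$pct_identity, stringsAsFactors = FALSE)
}

#' Cross-species specificity and sensitivity of paired gene lists
#'
#' Specificity is the percentage of the query-species list whose homologs
#' replicate in the subject-species list; sensitivity is the converse
#' percentage with the homology table inverted. Both are reported raw and
#' formatted at one decimal using the truncation convention (27/70 ->
#' 38.5).
#'
#' @inheritParams replicated_set
#' @return list with `specificity`, `sensitivity` (raw percentages),
#'   `specificity_1dp`, `sensitivity_1dp` (truncated to one decimal),
#'   `n_a`, `n_b`, `n_replicated_a`, `n_replicated_b`.
#' @export
specificity_sensitivity <- function(list_a, list_b, homology) {
  if (!length(list_a) || !length(list_b))
    stop("undefined metric: empty gene list")
  rep_a <- replicated_set(list_a, homology, list_b)
  rep_b <- replicated_set(list_b, .invert_homology(homology), list_a)
  list(
    specificity = 100 * length(rep_a) / length(list_a),
    sensitivity = 100 * length(rep_b) / length(list_b),
    specificity_1dp = percent_trunc1(length(rep_a), length(list_a)),
    sensitivity_1dp = percent_trunc1(length(rep_b), length(list_b)),
    n_a = length(list_a), n_b = length(list_b),
    n_replicated_a = length(rep_a), n_replicated_b = length(rep_b)
  )
}

#' Replication of seed-specificity per similarity bin
#'
#' Groups the counterpart-species gene models (homology subjects of the
#' query list) by similarity bin and reports, per bin, how many replicate
#' as seed-specific in the counterpart species. Subjects without
#' expression data can be excluded via `measured`, mirroring homologs with
#' no probe on the counterpart array.
#'
#' @inheritParams replicated_set
#' @param measured optional character vector of subject genes with
#'   expression data; subjects outside it are dropped from denominators.
#' @return data.frame (bin, n, n_replicated, pct); `pct` is the
#'   nearest-integer percentage, `NA` for an empty bin.
#' @export
replication_by_bin <- function(list_a, homology, list_b, measured = NULL) {
  h <- .informative_pairs(homology)
  h <- h[h$query %in% list_a, , drop = FALSE]
  if (!is.null(measured)) h <- h[h$subject %in% measured, , drop = FALSE]
  h$bin <- bin_similarity(h$pct_identity)
  out <- data.frame(bin = c("HS", "MS", "WS"), n = 0L, n_replicated = 0L,
                    pct = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    subj <- unique(h$subject[h$bin == out$bin[i]])
    out$n[i] <- length(subj)
    out$n_replicated[i] <- sum(subj %in% list_b)
    out$pct[i] <- if (out$n[i] > 0)
      percent_round(out$n_replicated[i], out$n[i]) else NA_real_
  }
  out
}

#' Table-2-style method comparison across species
#'
#' Computes cross-species specificity and sensitivity for matched method
#' lists (e.g. DDD-alone, array-alone, combined) of two species.
#'
#' @param lists_a named list of query-species gene vectors, one per method.
#' @param lists_b named list of subject-species gene vectors with the same
#'   names.
#' @param homology data.frame (query, subject, pct_identity).
#' @return data.frame with one row per method: method, n_a, n_b,
#'   n_replicated_a, n_replicated_b, specificity, sensitivity,
#'   specificity_1dp, sensitivity_1dp.
#' @export
compare_methods <- function(lists_a, lists_b, homology) {
  .check(identical(names(lists_a), names(lists_b)),
         "method lists must share names")
  rows <- lapply(names(lists_a), function(m) {
    s <- specificity_sensitivity(lists_a[[m]], lists_b[[m]], homology)
    data.frame(method = m, n_a = s$n_a, n_b = s$n_b,
               n_replicated_a = s$n_replicated_a,
               n_replicated_b = s$n_replicated_b,
               specificity = s$specificity, sensitivity = s$sensitivity,
               specificity_1dp = s$specificity_1dp,
               sensitivity_1dp = s$sensitivity_1dp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
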