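#' Intersect the DDD and microarray screens at the unigene level
#'
#' A unigene is array-positive when at least one of its retained probesets
#' is seed-specific. DDD-selected unigenes without any retained probeset
#' cannot be evaluated on the array: they are listed in `no_probeset` and
#' excluded from `combined` (neither accepted nor counted as rejected).
#'
#' @param ddd a `ddd_screen` object or a character vector of DDD-selected
#'   unigene ids.
#' @param calls the per-probeset calls data.frame from
#'   [seed_specific_calls()] / [array_screen()] (retained probesets only).
#' @param probeset_map data.frame (probeset_id, gene_id) covering every
#'   call probeset.
#' @return object of class `screen_sets`: list with `ddd_genes`,
#'   `array_genes`, `combined`, `no_probeset`.
#' @export
intersect_screens <- function(ddd, calls, probeset_map) {
  ddd_genes <- if (inherits(ddd, "ddd_screen")) selected_genes(ddd)
  else as.character(ddd)
  if (!all(calls$probeset_id %in% probeset_map$probeset_id))
    stop("probeset_map does not cover all call probesets")
  gene_of <- probeset_map$gene_id[match(calls$probeset_id,
                                        probeset_map$probeset_id)]
  with_probe <- unique(gene_of)
  array_genes <- unique(gene_of[calls$specific])
  out <- list(
    ddd_genes = ddd_genes,
    array_genes = array_genes,
    combined = intersect(ddd_genes, array_genes),
    no_probeset = setdiff(ddd_genes, with_probe)
  )
  class(out) <- "screen_sets"
  out
}

#' @export
print.screen_sets <- function(x, ...) {
  cat("Screen intersection:\n")
  cat("  DDD-selected unigenes:      ", length(x$ddd_genes), "\n")
  cat("  array-positive unigenes:    ", length(x$array_genes), "\n")
  cat("  combined (both screens):    ", length(x$combined), "\n")
  cat("  DDD genes with no probeset: ", length(x$no_probeset), "\n")
  invisible(x)
}

#' Annotation-class breakdown of a gene list
#'
#' Counts genes per annotation class (CG = characterized gene model,
#' SG = similar to a known protein, UG = unknown transcript) and reports
#' integer percentages rounded to the nearest whole percent (ties away
#' from zero), e.g. 108 of 407 prints as 27%.
#'
#' @param genes character vector of gene ids.
#' @param annotations data.frame (gene_id, annotation_class) covering every
#'   gene in `genes`.
#' @return data.frame (annotation_class, n, pct).
#' @export
breakdown_by_class <- function(genes, annotations) {
  cls <- annotations$annotation_class[match(genes, annotations$gene_id)]
  if (anyNA(cls))
    stop("missing annotation for gene(s): ",
         paste(utils::head(genes[is.na(cls)], 5), collapse = ", "))
  bad <- setdiff(unique(cls), c("CG", "SG", "UG"))
  if (length(bad)) stop("unknown annotation class: ", bad[1])
  lev <- intersect(c("CG", "SG", "UG"), unique(cls))
  n <- as.integer(table(factor(cls, levels = lev)))
  data.frame(annotation_class = lev, n = n,
             pct = percent_round(n, length(genes)),
             stringsAsFactors = FALSE)
}

#' Bin genes by unigene cluster size
#'
#' Cluster size is the gene's total EST count over both pools. Bins are
#' half-open `[lo, hi)` intervals from consecutive edges; the last bin is
#' open-ended, and sizes below the first edge are clamped into the first
#' bin. The per-bin fraction of CG gene models is reported alongside the
#' counts (characterization is easier for large clusters, so this ratio
#' typically rises with size).
#'
#' @param genes character vector of gene ids.
#' @param est_totals named numeric vector of per-gene total EST counts
#'   (names = gene ids), or a data.frame (gene_id, size).
#' @param annotations data.frame (gene_id, annotation_class).
#' @param bin_edges strictly increasing numeric edges; `Inf` as the final
#'   edge is allowed. Default `c(2, 4, 8, 16, 32, 64, 128, Inf)`.
#' @return data.frame (bin, lo, hi, n, n_cg, cg_ratio).
#' @export
bin_by_cluster_size <- function(genes, est_totals, annotations,
                                bin_edges = c(2, 4, 8, 16, 32, 64, 128, Inf)) {
  .check(all(diff(bin_edges) > 0), "bin_edges must be strictly increasing")
  if (is.data.frame(est_totals))
    est_totals <- stats::setNames(est_totals$size, est_totals$gene_id)
  size <- est_totals[genes]
  if (anyNA(size)) stop("missing EST total for some genes")
  edges <- bin_edges
  if (is.finite(edges[length(edges)])) edges <- c(edges, Inf)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  size <- pmax(size, lo[1])  # underflow clamps into the first bin
  bin <- findInterval(size, edges, rightmost.closed = FALSE)
  cls <- annotations$annotation_class[match(genes, annotations$gene_id)]
  n <- tabulate(bin, nbins = length(lo))
  n_cg <- tabulate(bin[cls == "CG"], nbins = length(lo))
  data.frame(
    bin = sprintf("[%g,%g)", lo, hi),
    lo = lo, hi = hi, n = n, n_cg = n_cg,
    cg_ratio = ifelse(n > 0, n_cg / n, NA_real_),
    stringsAsFactors = FALSE
  )
}
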