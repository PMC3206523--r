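#' Selection thresholds for the digital differential display screen
#'
#' The screen keeps a unigene when (i) its Fisher exact p-value is at most
#' `alpha`, (ii) its expression fraction in the non-seed pool is strictly
#' below `max_fraction_b`, and (iii) its seed-pool signal exceeds `fold`
#' times the non-seed signal (strictly). The fold criterion can be applied
#' to raw EST counts (`fold_basis = "counts"`, the default: `a > fold * b`)
#' or to pool fractions (`fraction_a > fold * fraction_b`); the two differ
#' materially when the pools have unequal totals.
#'
#' @param alpha significance level of the Fisher exact test (default 0.05).
#' @param max_fraction_b strict upper bound on the non-seed pool fraction
#'   (default 0.00005).
#' @param fold minimum seed-over-non-seed enrichment, strict (default 4;
#'   a 3-fold setting is the convention for rice, where fewer seed
#'   libraries are available).
#' @param fold_basis `"counts"` or `"fractions"`.
#' @return list of class `ddd_thresholds`.
#' @export
ddd_thresholds <- function(alpha = 0.05, max_fraction_b = 0.00005,
                           fold = 4, fold_basis = c("counts", "fractions")) {
  fold_basis <- match.arg(fold_basis)
  .check(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  .check(fold > 1, "fold must exceed 1")
  .check(max_fraction_b > 0, "max_fraction_b must be positive")
  structure(list(alpha = alpha, max_fraction_b = max_fraction_b,
                 fold = fold, fold_basis = fold_basis),
            class = "ddd_thresholds")
}

#' Pool EST counts per gene into the two-pool 2x2 margins
#'
#' Sums each gene's EST counts over the seed-pool (A) libraries and the
#' non-seed-pool (B) libraries. Pool totals `A` and `B` come from the
#' catalog's planned library sizes, so an incomplete count table (genes
#' missing) still uses the correct pool denominators.
#'
#' @param est an `est_counts` object (see [sample_est_counts()] or
#'   [read_est_counts()]).
#' @return data.frame with columns `gene_id`, `a`, `b`, `A`, `B`.
#' @export
pool_counts <- function(est) {
  stopifnot(inherits(est, "est_counts"))
  cat_ <- est$catalog
  in_a <- cat_$pool == "A"
  in_b <- cat_$pool == "B"
  if (!any(in_a) || !any(in_b)) stop("both pools must be nonempty")
  A <- sum(cat_$n_ests[in_a])
  B <- sum(cat_$n_ests[in_b])
  if (A <= 0 || B <= 0) stop("a pool has zero total ESTs")
  cols <- colnames(est$counts)
  a <- rowSums(est$counts[, cat_$library_id[in_a][cat_$library_id[in_a] %in% cols],
                          drop = FALSE])
  b <- rowSums(est$counts[, cat_$library_id[in_b][cat_$library_id[in_b] %in% cols],
                          drop = FALSE])
  data.frame(gene_id = rownames(est$counts), a = as.integer(a),
             b = as.integer(b), A = A, B = B, stringsAsFactors = FALSE)
}

# two-sided exact p for one 2x2 pool table, by summation of hypergeometric
# point probabilities over the support; ties with the observed table's
# probability are included at relative tolerance 1e-12
.fisher_one <- function(a, A, b, B) {
  if (A <= 0 || B <= 0 || a < 0 || b < 0 || a > A || b > B)
    stop("invalid pool counts: need 0 <= a <= A, 0 <= b <= B, A,B > 0")
  m <- a + b
  if (m == 0 || m == A + B) return(1)
  x <- max(0, m - B):min(m, A)
  d <- stats::dhyper(x, A, B, m)
  dobs <- stats::dhyper(a, A, B, m)
  min(1, sum(d[d <= dobs * (1 + 1e-12)]))
}

#' Two-sided Fisher exact p-value for a pooled 2x2 EST table
#'
#' Tests the table `[[a, A - a], [b, B - b]]` -- a gene's ESTs versus the
#' rest, in the seed pool versus the non-seed pool. The p-value is the sum
#' of hypergeometric point probabilities not exceeding the observed table's
#' probability (two-sided, with ties included at a relative tolerance of
#' 1e-12). Degenerate margins (no ESTs for the gene at all) give p = 1.
#'
#' @param a,b the gene's EST counts in pools A and B.
#' @param A,B pool total EST counts. All four arguments are recycled.
#' @return p-value(s) in (0, 1].
#' @examples
#' fisher_exact_p(40, 151632, 2, 473145)
#' @export
fisher_exact_p <- function(a, A, b, B) {
  n <- max(length(a), length(b), length(A), length(B))
  a <- rep_len(a, n); b <- rep_len(b, n)
  A <- rep_len(A, n); B <- rep_len(B, n)
  vapply(seq_len(n), function(i) .fisher_one(a[i], A[i], b[i], B[i]),
         numeric(1))
}

#' Apply the DDD selection rule to pooled counts
#'
#' @param pcs data.frame from [pool_counts()].
#' @param thr a [ddd_thresholds()] object.
#' @return data.frame with `gene_id`, `a`, `b`, `fraction_a`, `fraction_b`,
#'   `p_value`, `selected`. Genes absent from both pools are retained with
#'   p = 1 and `selected = FALSE`, so bookkeeping over the input gene set
#'   is exact.
#' @export
ddd_select <- function(pcs, thr = ddd_thresholds()) {
  stopifnot(inherits(thr, "ddd_thresholds"))
  .check(all(c("gene_id", "a", "b", "A", "B") %in% names(pcs)),
         "pcs must come from pool_counts()")
  fraction_a <- pcs$a / pcs$A
  fraction_b <- pcs$b / pcs$B
  p <- fisher_exact_p(pcs$a, pcs$A, pcs$b, pcs$B)
  fold_ok <- if (thr$fold_basis == "counts") pcs$a > thr$fold * pcs$b
  else fraction_a > thr$fold * fraction_b
  selected <- p <= thr$alpha & fraction_b < thr$max_fraction_b & fold_ok
  data.frame(gene_id = pcs$gene_id, a = pcs$a, b = pcs$b,
             fraction_a = fraction_a, fraction_b = fraction_b,
             p_value = p, selected = selected, stringsAsFactors = FALSE)
}

#' Run the digital differential display screen on an EST count table
#'
#' Pools counts ([pool_counts()]), computes the two-sided Fisher exact
#' p-value per gene ([fisher_exact_p()]) and applies the selection rule
#' ([ddd_select()]).
#'
#' @param est an `est_counts` object.
#' @param thr a [ddd_thresholds()] object.
#' @return object of class `ddd_screen`: list with `results` (the
#'   [ddd_select()] data.frame), `thresholds`, and pool totals `A`, `B`.
#' @export
ddd_screen <- function(est, thr = ddd_thresholds()) {
  pcs <- pool_counts(est)
  res <- ddd_select(pcs, thr)
  out <- list(results = res, thresholds = thr,
              A = pcs$A[1], B = pcs$B[1])
  class(out) <- "ddd_screen"
  out
}

#' @export
print.ddd_screen <- function(x, ...) {
  cat("DDD screen:", nrow(x$results), "unigenes tested;",
      sum(x$results$selected), "selected\n")
  cat(sprintf("  pool totals A = %d, B = %d\n", x$A, x$B))
  cat(sprintf(
    "  rule: p <= %g, fraction_b < %g, %s-based fold > %g\n",
    x$thresholds$alpha, x$thresholds$max_fraction_b,
    x$thresholds$fold_basis, x$thresholds$fold))
  invisible(x)
}

#' @export
summary.ddd_screen <- function(object, ...) {
  res <- object$results
  structure(list(n_tested = nrow(res),
                 n_selected = sum(res$selected),
                 n_p_pass = sum(res$p_value <= object$thresholds$alpha),
                 thresholds = object$thresholds),
            class = "summary.ddd_screen")
}

#' @export
print.summary.ddd_screen <- function(x, ...) {
  cat("tested:", x$n_tested, " p-criterion pass:", x$n_p_pass,
      " selected:", x$n_selected, "\n")
  invisible(x)
}

#' Selected gene identifiers of a DDD screen
#'
#' @param x a `ddd_screen` object.
#' @return character vector of selected unigene ids.
#' @export
selected_genes <- function(x) {
  stopifnot(inherits(x, "ddd_screen"))
  x$results$gene_id[x$results$selected]
}
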