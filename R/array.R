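#' Remove cross-hybridizing and wrong-orientation probesets
#'
#' Drops probesets whose identifier ends in `_s_at`, `_x_at` or `_a_at`
#' (designs known to cross-hybridize) or contains the `.A1` design token
#' (predominantly wrong-orientation probes). All other probesets are kept
#' in input order. The operation is idempotent.
#'
#' @param mapping either a character vector of probeset identifiers or a
#'   data.frame with a `probeset_id` column (e.g. a probeset-to-unigene
#'   map).
#' @return the retained identifiers / rows, in input order.
#' @examples
#' filter_probesets(c("Ta.1_at", "Ta.2_s_at", "Ta.3_x_at"))
#' @export
filter_probesets <- function(mapping) {
  ids <- if (is.data.frame(mapping)) mapping$probeset_id else mapping
  .check(is.character(ids) && !anyNA(ids) && all(nzchar(ids)),
         "probeset identifiers must be nonempty strings")
  drop <- grepl("(_s_at|_x_at|_a_at)$", ids) |
    grepl(".A1", ids, fixed = TRUE)
  if (is.data.frame(mapping)) mapping[!drop, , drop = FALSE] else ids[!drop]
}

#' Collapse replicate samples to one column per organ
#'
#' Averages the log2 replicate columns of each organ arithmetically (on the
#' log2 scale, i.e. a geometric mean of intensities).
#'
#' @param expr an `expr_matrix` object.
#' @return object of class `organ_matrix`: list with `values` (probeset x
#'   organ matrix of log2 means) and `organs` (the organ panel).
#' @export
collapse_replicates <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  panel <- expr$organs
  vals <- matrix(NA_real_, nrow = nrow(expr$values), ncol = nrow(panel),
                 dimnames = list(rownames(expr$values), panel$organ))
  for (j in seq_len(nrow(panel))) {
    cols <- expr$samples$sample_id[expr$samples$organ == panel$organ[j]]
    if (!length(cols))
      stop("organ with zero replicate columns: ", panel$organ[j])
    vals[, j] <- rowMeans(expr$values[, cols, drop = FALSE])
  }
  structure(list(values = vals, organs = panel), class = "organ_matrix")
}

#' Call seed-specific probesets by a strict linear-scale fold rule
#'
#' A probeset is seed-specific when its best seed-organ signal exceeds
#' `fold_threshold` times its best non-seed-organ signal on the linear
#' intensity scale (`2^log2value`); the comparison is strict, so an exact
#' 4-fold ratio is rejected. The developmental stage assigned is that of
#' the maximizing seed organ (ties broken by organ panel order).
#'
#' @param om an `organ_matrix` from [collapse_replicates()].
#' @param probe_map data.frame (probeset_id, gene_id) covering the matrix
#'   rows; rows of `om` absent from the map get `NA` unigene ids.
#' @param fold_threshold minimum fold enrichment, strict (default 4).
#' @return data.frame with one row per probeset: `probeset_id`,
#'   `unigene_id`, `seed_value`, `max_other`, `fold`, `specific`, `stage`
#'   (`NA` when not specific).
#' @export
seed_specific_calls <- function(om, probe_map = NULL, fold_threshold = 4) {
  stopifnot(inherits(om, "organ_matrix"))
  panel <- om$organs
  if (!any(panel$is_seed) || !any(!panel$is_seed))
    stop("organ panel needs at least one seed and one non-seed organ")
  lin <- 2^om$values
  seed_cols <- which(panel$is_seed)
  other_cols <- which(!panel$is_seed)
  seed_sub <- lin[, seed_cols, drop = FALSE]
  best_seed <- max.col(seed_sub, ties.method = "first")
  seed_value <- seed_sub[cbind(seq_len(nrow(lin)), best_seed)]
  max_other <- apply(lin[, other_cols, drop = FALSE], 1, max)
  fold <- seed_value / max_other
  specific <- seed_value > fold_threshold * max_other
  stage <- panel$stage[seed_cols][best_seed]
  unigene <- if (is.null(probe_map)) NA_character_
  else probe_map$gene_id[match(rownames(lin), probe_map$probeset_id)]
  data.frame(probeset_id = rownames(lin), unigene_id = unigene,
             seed_value = seed_value, max_other = max_other, fold = fold,
             specific = specific,
             stage = ifelse(specific, stage, NA_character_),
             stringsAsFactors = FALSE)
}

#' Sample Pearson correlation of two profiles
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  .check(length(x) == length(y), "profiles must have equal length")
  .check(length(x) >= 3, "profiles must have length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance profile")
  as.numeric(stats::cor(x, y))
}

#' Find profile neighbors of a seed probeset set
#'
#' Returns the probesets outside the seed set whose organ profile has
#' Pearson correlation at least `min_r` with at least one seed probeset.
#' Constant (zero-variance) profiles are never neighbors.
#'
#' @param om an `organ_matrix`.
#' @param seed_probesets character vector, a subset of the matrix rows; an
#'   empty set yields an empty result.
#' @param min_r minimum correlation (default 0.8, inclusive).
#' @return character vector of neighbor probeset ids, in matrix row order.
#' @export
profile_neighbors <- function(om, seed_probesets, min_r = 0.8) {
  stopifnot(inherits(om, "organ_matrix"))
  if (!length(seed_probesets)) return(character(0))
  .check(all(seed_probesets %in% rownames(om$values)),
         "seed probesets must be rows of the matrix")
  others <- setdiff(rownames(om$values), seed_probesets)
  if (!length(others)) return(character(0))
  ok_var <- apply(om$values, 1, stats::sd) > 0
  seeds <- seed_probesets[ok_var[seed_probesets]]
  cand <- others[ok_var[others]]
  if (!length(seeds) || !length(cand)) return(character(0))
  r <- stats::cor(t(om$values[cand, , drop = FALSE]),
                  t(om$values[seeds, , drop = FALSE]))
  cand[apply(r, 1, max) >= min_r]
}

#' Agglomerative clustering of expression profiles by Pearson distance
#'
#' Clusters probeset rows with distance `1 - Pearson r` and the given
#' linkage (average by default), for heat-map row ordering.
#'
#' @param om an `organ_matrix`, or a plain numeric matrix with row names;
#'   needs >= 2 rows, none constant.
#' @param linkage hclust agglomeration method (default "average").
#' @return object of class `profile_clustering`: list with `order` (leaf
#'   labels), `merge`, `height` and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(om, linkage = "average") {
  vals <- if (inherits(om, "organ_matrix")) om$values else om
  .check(is.matrix(vals) && nrow(vals) >= 2, "need >= 2 profiles")
  if (any(apply(vals, 1, stats::sd) == 0))
    stop("undefined distance: constant profile row (drop or jitter it)")
  d <- stats::as.dist(1 - stats::cor(t(vals)))
  hc <- stats::hclust(d, method = linkage)
  structure(list(order = rownames(vals)[hc$order], merge = hc$merge,
                 height = hc$height, hclust = hc),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("Pearson-distance clustering of", length(x$order), "profiles;",
      "leaf order:\n ", paste(utils::head(x$order, 10), collapse = ", "),
      if (length(x$order) > 10) "..." else "", "\n")
  invisible(x)
}

#' Run the microarray organ-specificity screen
#'
#' Filters cross-hybridizing probesets ([filter_probesets()]), averages
#' replicates ([collapse_replicates()]) and applies the strict fold rule
#' ([seed_specific_calls()]).
#'
#' @param expr an `expr_matrix` object.
#' @param fold_threshold strict minimum linear fold (default 4).
#' @return object of class `array_screen`: list with `calls` (per retained
#'   probeset), `retained_map`, `organ_matrix`, `fold_threshold`.
#' @export
array_screen <- function(expr, fold_threshold = 4) {
  stopifnot(inherits(expr, "expr_matrix"))
  keep <- filter_probesets(expr$probe_map)
  om <- collapse_replicates(expr)
  om$values <- om$values[rownames(om$values) %in% keep$probeset_id, ,
                         drop = FALSE]
  calls <- seed_specific_calls(om, keep, fold_threshold)
  structure(list(calls = calls, retained_map = keep, organ_matrix = om,
                 fold_threshold = fold_threshold),
            class = "array_screen")
}

#' @export
print.array_screen <- function(x, ...) {
  cat("Array screen:", nrow(x$calls), "retained probesets;",
      sum(x$calls$specific), "seed-specific (fold >",
      x$fold_threshold, "linear, strict)\n")
  spec <- x$calls[x$calls$specific, ]
  if (nrow(spec)) {
    tb <- table(spec$stage)
    cat("  stage of maximizing seed organ:",
        paste(names(tb), tb, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}
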