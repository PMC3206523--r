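# End-to-end orchestration of the combined screen on synthetic data:
# generate two species, run the DDD and array screens on each, intersect,
# compare across species over a sampled homology map, and test GO
# enrichment of the combined list.

# stage/class/recovery summaries for one species
.screen_species <- function(data, thr, fold_threshold) {
  dd <- ddd_screen(data$est, thr)
  ar <- array_screen(data$expr, fold_threshold)
  sets <- intersect_screens(dd, ar$calls, ar$retained_map)
  list(ddd = dd, array = ar, sets = sets)
}

# per-unigene stage of specificity: the stage(s) of its specific probesets;
# mixed stages are reported as "both/other" rather than forced binary
.stage_breakdown <- function(calls, genes) {
  spec <- calls[calls$specific & calls$unigene_id %in% genes, , drop = FALSE]
  per_gene <- vapply(split(spec$stage, spec$unigene_id), function(st) {
    st <- unique(st[!is.na(st)])
    if (length(st) == 1) st else "both/other"
  }, character(1))
  tb <- table(per_gene)
  data.frame(stage = names(tb), n = as.integer(tb), stringsAsFactors = FALSE)
}

.recovery <- function(sets, truth, genes_with_probes) {
  planted <- truth$genes$gene_id[truth$genes$is_seed_specific]
  evaluable <- intersect(planted, genes_with_probes)
  combined <- sets$combined
  list(
    n_planted = length(planted),
    n_evaluable = length(evaluable),
    n_recovered = length(intersect(combined, planted)),
    precision = if (length(combined))
      length(intersect(combined, planted)) / length(combined) else NA_real_,
    sensitivity = if (length(evaluable))
      length(intersect(combined, evaluable)) / length(evaluable)
    else NA_real_,
    sensitivity_all_planted = if (length(planted))
      length(intersect(combined, planted)) / length(planted) else NA_real_
  )
}

#' Run the full combined screen on synthetic data
#'
#' Generates a query species (wheat-like, pool-fold 4 by default) and a
#' subject species (rice-like, pool-fold 3), screens both with DDD and the
#' microarray fold rule, intersects at the unigene level, evaluates
#' recovery of the planted truth, computes Table-2-style cross-species
#' specificity/sensitivity for the DDD-alone, array-alone and combined
#' lists, replication per similarity bin, and GO enrichment of the
#' combined list.
#'
#' @param config [synth_config()] for the query species.
#' @param config_b optional config for the subject species; by default the
#'   query config with gene prefix "Os." and an offset RNG seed.
#' @param thresholds [ddd_thresholds()] for the query species.
#' @param thresholds_b [ddd_thresholds()] for the subject species
#'   (default fold 3).
#' @param fold_threshold strict linear fold for the array rule (default 4).
#' @param go_alpha enrichment cutoff (default 0.05).
#' @param out_dir optional directory; when given, all stage tables and the
#'   JSON report are written there.
#' @param verbose log stage row counts via `message()`.
#' @return object of class `seed_screen_run` (a nested list report); see
#'   `print()` for the headline counts.
#' @export
run_pipeline <- function(config = synth_config(),
                         config_b = NULL,
                         thresholds = ddd_thresholds(),
                         thresholds_b = ddd_thresholds(fold = 3),
                         fold_threshold = 4,
                         go_alpha = 0.05,
                         out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(config_b)) {
    cb <- unclass(config)
    cb$gene_prefix <- "Os."
    cb$rng_seed <- config$rng_seed + 101L
    config_b <- do.call(synth_config, cb)
  }
  say <- function(...) if (verbose) message(...)

  data_a <- synth_dataset(config)
  data_b <- synth_dataset(config_b)
  homology <- sample_homology(data_a$truth, data_b$truth, config)
  say("generated ", config$n_genes, " + ", config_b$n_genes,
      " genes; ", nrow(homology), " homolog pairs")

  sa <- .screen_species(data_a, thresholds, fold_threshold)
  sb <- .screen_species(data_b, thresholds_b, fold_threshold)
  say("query species: ", length(sa$sets$ddd_genes), " DDD / ",
      length(sa$sets$array_genes), " array / ",
      length(sa$sets$combined), " combined")

  species_report <- function(data, s) {
    pcs <- data.frame(gene_id = s$ddd$results$gene_id,
                      size = s$ddd$results$a + s$ddd$results$b)
    ann <- data$truth$genes
    list(
      n_genes = nrow(ann),
      n_ddd_selected = length(s$sets$ddd_genes),
      n_probesets = nrow(data$expr$probe_map),
      n_probesets_retained = nrow(s$array$retained_map),
      n_array_specific_probesets = sum(s$array$calls$specific),
      n_array_specific_unigenes = length(s$sets$array_genes),
      n_combined = length(s$sets$combined),
      n_no_probeset = length(s$sets$no_probeset),
      class_breakdown_ddd = breakdown_by_class(s$sets$ddd_genes, ann),
      class_breakdown_combined = if (length(s$sets$combined))
        breakdown_by_class(s$sets$combined, ann) else NULL,
      stage_breakdown = .stage_breakdown(s$array$calls, s$sets$combined),
      size_bins = bin_by_cluster_size(s$sets$ddd_genes, pcs, ann),
      recovery = .recovery(s$sets, data$truth,
                           unique(s$array$retained_map$gene_id))
    )
  }
  rep_a <- species_report(data_a, sa)
  rep_b <- species_report(data_b, sb)

  lists_a <- list(ddd_alone = sa$sets$ddd_genes,
                  array_alone = sa$sets$array_genes,
                  combined = sa$sets$combined)
  lists_b <- list(ddd_alone = sb$sets$ddd_genes,
                  array_alone = sb$sets$array_genes,
                  combined = sb$sets$combined)
  comparable <- all(lengths(lists_a) > 0) && all(lengths(lists_b) > 0)
  comparison <- if (comparable) compare_methods(lists_a, lists_b, homology)
  else NULL
  measured_b <- unique(sb$array$retained_map$gene_id)
  by_bin <- replication_by_bin(sa$sets$combined, homology,
                               sb$sets$combined, measured = measured_b)

  enr <- go_enrich(sa$sets$combined, data_a$truth$genes$gene_id,
                   data_a$go, alpha = go_alpha)
  seed_term <- attr(data_a$go, "seed_term")

  report <- list(
    config = list(query = .config_echo(config),
                  subject = .config_echo(config_b),
                  ddd_thresholds = unclass(thresholds),
                  ddd_thresholds_subject = unclass(thresholds_b),
                  array_fold_threshold = fold_threshold,
                  go_alpha = go_alpha),
    query = rep_a,
    subject = rep_b,
    cross_species = list(comparison = comparison,
                         replication_by_bin = by_bin),
    enrichment = list(
      n_terms_tested = nrow(enr),
      n_enriched = sum(enr$enriched),
      seed_term = seed_term,
      seed_term_p = if (seed_term %in% enr$go_id)
        enr$p_value[enr$go_id == seed_term] else NA_real_,
      seed_term_rank = if (seed_term %in% enr$go_id)
        which(enr$go_id == seed_term) else NA_integer_,
      top_terms = utils::head(enr, 10)
    ),
    version = as.character(utils::packageVersion("seedscreen"))
  )
  class(report) <- "seed_screen_run"
  .check_report_consistency(report)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .write_tsv(sa$ddd$results, file.path(out_dir, "ddd_results.tsv"))
    .write_tsv(sa$array$calls, file.path(out_dir, "array_calls.tsv"))
    .write_tsv(data.frame(gene_id = sa$sets$combined),
               file.path(out_dir, "combined_genes.tsv"))
    write_homology(homology, file.path(out_dir, "homology.tsv"))
    if (!is.null(comparison))
      .write_tsv(comparison, file.path(out_dir, "method_comparison.tsv"))
    .write_tsv(by_bin, file.path(out_dir, "replication_by_bin.tsv"))
    .write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    jsonlite::write_json(.jsonable(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE, null = "null", na = "null")
    say("stage outputs written to ", out_dir)
  }
  report
}

# config echo without closures/frames so the report is JSON-serializable
.config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$identity_sampler <- NULL
  cfg
}

.jsonable <- function(x) {
  if (inherits(x, "seed_screen_run")) x <- unclass(x)
  x
}

# the headline counts must respect the set algebra of the screens
.check_report_consistency <- function(report) {
  for (sp in list(report$query, report$subject)) {
    .check(sp$n_combined <= min(sp$n_ddd_selected,
                                sp$n_array_specific_unigenes),
           "inconsistent report: combined exceeds a single screen")
    .check(sp$n_probesets_retained <= sp$n_probesets,
           "inconsistent report: retained probesets exceed total")
    .check(sp$n_array_specific_probesets <= sp$n_probesets_retained,
           "inconsistent report: specific probesets exceed retained")
  }
  invisible(TRUE)
}

#' @export
print.seed_screen_run <- function(x, ...) {
  q <- x$query
  cat("Combined seed-specificity screen (synthetic run)\n")
  cat(sprintf("  query species: %d genes, %d DDD-selected, %d array-positive, %d combined (%d without probeset)\n",
              q$n_genes, q$n_ddd_selected, q$n_array_specific_unigenes,
              q$n_combined, q$n_no_probeset))
  if (nrow(q$stage_breakdown))
    cat("  stage of combined genes:",
        paste(q$stage_breakdown$stage, q$stage_breakdown$n,
              sep = " = ", collapse = ", "), "\n")
  r <- q$recovery
  cat(sprintf("  recovery vs planted truth: precision %.3f, sensitivity %.3f (%d planted, %d evaluable)\n",
              r$precision, r$sensitivity, r$n_planted, r$n_evaluable))
  cmp <- x$cross_species$comparison
  if (!is.null(cmp)) {
    cat("  cross-species replication (spec%/sens%, one-decimal truncated):\n")
    for (i in seq_len(nrow(cmp)))
      cat(sprintf("    %-12s %5.1f / %5.1f\n", cmp$method[i],
                  cmp$specificity_1dp[i], cmp$sensitivity_1dp[i]))
  }
  cat(sprintf("  GO enrichment: %d/%d terms at p < %g; seed-biased term p = %.3g (rank %s)\n",
              x$enrichment$n_enriched, x$enrichment$n_terms_tested,
              x$config$go_alpha, x$enrichment$seed_term_p,
              x$enrichment$seed_term_rank))
  invisible(x)
}
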