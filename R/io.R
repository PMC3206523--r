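# Plain-text interchange: every table is TSV with a header row; the run
# report is JSON. Readers reconstruct the same classed objects the
# generator produces, so file-based and in-memory pipelines are equivalent.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an EST count table and its library catalog
#'
#' @param est an `est_counts` object.
#' @param counts_file path for the gene x library count TSV (first column
#'   `gene_id`).
#' @param catalog_file path for the library catalog TSV.
#' @return invisibly, the two paths.
#' @export
write_est_counts <- function(est, counts_file, catalog_file) {
  stopifnot(inherits(est, "est_counts"))
  df <- data.frame(gene_id = rownames(est$counts), est$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, counts_file)
  .write_tsv(est$catalog, catalog_file)
  invisible(c(counts_file, catalog_file))
}

#' Read an EST count table and library catalog
#'
#' @param counts_file,catalog_file paths written by [write_est_counts()]
#'   (or equivalent: counts TSV with a `gene_id` first column, catalog TSV
#'   with library_id/tissue/pool/n_ests).
#' @return an `est_counts` object.
#' @export
read_est_counts <- function(counts_file, catalog_file) {
  df <- .read_tsv(counts_file)
  catalog <- .read_tsv(catalog_file)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene_id
  structure(list(counts = counts, catalog = catalog), class = "est_counts")
}

#' Write an expression matrix with its sample, organ and probeset maps
#'
#' @param expr an `expr_matrix` object.
#' @param dir output directory; writes `expression.tsv`, `samples.tsv`,
#'   `organs.tsv`, `probe_map.tsv`.
#' @return invisibly, the directory.
#' @export
write_expression <- function(expr, dir) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- data.frame(probeset_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, file.path(dir, "expression.tsv"))
  .write_tsv(expr$samples, file.path(dir, "samples.tsv"))
  .write_tsv(expr$organs, file.path(dir, "organs.tsv"))
  .write_tsv(expr$probe_map, file.path(dir, "probe_map.tsv"))
  invisible(dir)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param dir directory holding `expression.tsv`, `samples.tsv`,
#'   `organs.tsv`, `probe_map.tsv`.
#' @return an `expr_matrix` object.
#' @export
read_expression <- function(dir) {
  df <- .read_tsv(file.path(dir, "expression.tsv"))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$probeset_id
  organs <- .read_tsv(file.path(dir, "organs.tsv"))
  organs$is_seed <- as.logical(organs$is_seed)
  organs$stage <- as.character(organs$stage)
  organs$stage[organs$stage %in% c("NA", "")] <- NA_character_
  structure(list(values = values,
                 samples = .read_tsv(file.path(dir, "samples.tsv")),
                 organs = organs,
                 probe_map = .read_tsv(file.path(dir, "probe_map.tsv"))),
            class = "expr_matrix")
}

#' Write / read a homology table
#'
#' @param homology data.frame (query, subject, pct_identity).
#' @param path TSV path.
#' @return `write_homology` returns the path invisibly; `read_homology`
#'   returns a `homology_table` data.frame.
#' @export
write_homology <- function(homology, path) {
  .write_tsv(homology, path)
  invisible(path)
}

#' @rdname write_homology
#' @export
read_homology <- function(path) {
  out <- .read_tsv(path)
  class(out) <- c("homology_table", "data.frame")
  out
}

#' Write / read a gene-to-GO annotation table
#'
#' @param annotation data.frame (gene_id, go_id).
#' @param path TSV path.
#' @return `write_annotation` returns the path invisibly;
#'   `read_annotation` the data.frame.
#' @export
write_annotation <- function(annotation, path) {
  .write_tsv(annotation, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) .read_tsv(path)

#' Write all synthetic inputs of one species to a directory
#'
#' Emits the library catalog, EST counts, expression bundle, annotation
#' table and a truth JSON (gene, planted flag, annotation class).
#'
#' @param data a `synth_data` object from [synth_dataset()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_synth_data <- function(data, dir) {
  stopifnot(inherits(data, "synth_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_est_counts(data$est, file.path(dir, "est_counts.tsv"),
                   file.path(dir, "library_catalog.tsv"))
  write_expression(data$expr, dir)
  write_annotation(data$go, file.path(dir, "go_annotation.tsv"))
  jsonlite::write_json(data$truth$genes, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
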