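#' Default EST library plan
#'
#' A two-pool catalog of EST libraries: pool A holds seed-derived libraries
#' (endosperm, embryo, whole seed, kernel, grain; 151,632 ESTs in total) and
#' pool B the non-seed libraries (callus, crown, leaf, shoot, root,
#' seedlings, heads, liquid-cultured tissue, sheath, spike, floral organs,
#' young spikelets; 473,145 ESTs). Each tissue group is represented as one
#' library whose size is the group total.
#'
#' @return data.frame with columns `library_id`, `tissue`, `pool`, `n_ests`.
#' @export
default_library_plan <- function() {
  data.frame(
    library_id = sprintf("LIB%02d", 1:17),
    tissue = c("endosperm", "seed embryo", "seed", "kernel", "grain",
               "callus", "crown", "leaf", "shoot", "root", "seedlings",
               "heads", "liquid cultured tissue", "sheath", "spike",
               "floral organs", "young spikelets"),
    pool = c(rep("A", 5), rep("B", 12)),
    n_ests = c(11346L, 4463L, 67394L, 13850L, 54579L,
               9685L, 14529L, 76992L, 94514L, 169382L, 2305L, 5143L,
               10164L, 1068L, 26307L, 60963L, 2093L),
    stringsAsFactors = FALSE
  )
}

#' Default microarray organ panel
#'
#' Seven vegetative/floral organs plus three seed samples covering two
#' developmental stages: the 3-5 DPA (days post-anthesis) coenocytic
#' caryopsis and the 22 DPA grain-filling embryo and endosperm.
#'
#' @return data.frame with columns `organ`, `is_seed`, `stage`.
#' @export
default_organ_panel <- function() {
  data.frame(
    organ = c("root", "leaf", "crown", "immature inflorescence",
              "floral bracts", "anthers", "pistil",
              "caryopsis 3-5 DPA", "embryo 22 DPA", "endosperm 22 DPA"),
    is_seed = c(rep(FALSE, 7), TRUE, TRUE, TRUE),
    stage = c(rep(NA_character_, 7), "3-5 DPA", "22 DPA", "22 DPA"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every parameter of the generator. Defaults describe
#' a wheat-like study: the full two-pool library plan of
#' [default_library_plan()] (151,632 seed vs 473,145 non-seed ESTs), a
#' ten-organ array panel with two seed stages and three replicates per
#' sample, 500 unigenes of which 25 are planted seed-specific.
#'
#' @param n_genes number of unigenes to simulate.
#' @param n_seed_specific number of planted seed-specific genes.
#' @param n_ddd_decoys number of planted EST-screen false positives: genes
#'   expressed in seed plus organs present only on the array panel (e.g.
#'   anthers, pistil), which the EST library pools cannot see. They pass
#'   the DDD rule but fail the array fold rule, emulating the screen's
#'   documented single-assay false positives (default 20).
#' @param n_array_decoys number of planted array-screen false positives:
#'   genes expressed in seed plus tissues present only in the EST
#'   libraries (e.g. callus, shoot), invisible to the array panel. They
#'   pass the array rule but fail the DDD pool-fraction rule (default 20).
#' @param library_plan data.frame(library_id, tissue, pool, n_ests); pools
#'   must be exactly "A" (seed) and "B" (non-seed).
#' @param organ_panel data.frame(organ, is_seed, stage); must contain at
#'   least one non-seed organ and seed organs spanning >= 2 stages.
#' @param replicates_per_sample array replicates per organ (default 3).
#' @param effect_size guaranteed minimum seed/non-seed expression ratio of a
#'   planted gene (> 1; default 8).
#' @param seed_leak mean residual off-target weight of a planted gene,
#'   relative to its per-tissue seed weight (default 0.002, i.e. planted
#'   genes are essentially silent outside the seed; always capped at
#'   `1/effect_size`).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   log2 expression scale (default 0.3).
#' @param array_floor additive intensity floor (linear scale) emulating the
#'   array detection limit, so log2 values stay finite.
#' @param suffix_fraction fraction of genes given an extra cross-hybridizing
#'   probeset suffixed `_s_at`/`_x_at`/`_a_at`/`.A1` (default 0.2).
#' @param no_probeset_fraction fraction of genes with no probeset on the
#'   array at all (default 0.2, mirroring the share of screened unigenes
#'   with no chip representation).
#' @param homology_fraction fraction of genes given a cross-species
#'   counterpart (default 0.6).
#' @param conservation probability that a paired planted gene maps to a
#'   planted counterpart (default 0.65).
#' @param identity_range percent-identity range for sampled homolog pairs
#'   (default c(46, 100), i.e. all pairs above the 45% reporting floor).
#' @param identity_sampler optional function(n) returning n percent
#'   identities in (45, 100]; overrides `identity_range`.
#' @param go_n_terms size of the random GO vocabulary (default 25).
#' @param go_mean_terms mean number of random term annotations per gene.
#' @param go_base_rate baseline annotation rate of the seed-biased term.
#' @param go_bias preferential annotation of the seed-biased term to planted
#'   genes, in `[0, 1]`: 0 = no preference, 1 = planted genes only.
#' @param gene_prefix prefix for generated gene identifiers.
#' @param rng_seed integer seed; every generator derives its own stream
#'   from it, so each table is reproducible independently.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 500,
                         n_seed_specific = 25,
                         n_ddd_decoys = 20,
                         n_array_decoys = 20,
                         library_plan = default_library_plan(),
                         organ_panel = default_organ_panel(),
                         replicates_per_sample = 3,
                         effect_size = 8,
                         seed_leak = 0.002,
                         noise_sd = 0.3,
                         array_floor = 1e-4,
                         suffix_fraction = 0.2,
                         no_probeset_fraction = 0.2,
                         homology_fraction = 0.6,
                         conservation = 0.65,
                         identity_range = c(46, 100),
                         identity_sampler = NULL,
                         go_n_terms = 25,
                         go_mean_terms = 2,
                         go_base_rate = 0.1,
                         go_bias = 0.8,
                         gene_prefix = "Ta.",
                         rng_seed = 1L) {
  .check(n_genes >= 1, "n_genes must be positive")
  .check(n_seed_specific >= 0, "n_seed_specific must be >= 0")
  if (n_seed_specific > n_genes)
    stop("invalid config: n_seed_specific exceeds n_genes")
  .check(n_ddd_decoys >= 0 && n_array_decoys >= 0,
         "decoy counts must be nonnegative")
  if (n_seed_specific + n_ddd_decoys + n_array_decoys > n_genes)
    stop("invalid config: planted genes and decoys exceed n_genes")
  .check(all(c("library_id", "tissue", "pool", "n_ests") %in%
               names(library_plan)), "library_plan is missing columns")
  .check(all(library_plan$pool %in% c("A", "B")),
         "library pools must be 'A' or 'B'")
  .check(all(c("A", "B") %in% library_plan$pool),
         "both pools must be represented in the library plan")
  if (any(library_plan$n_ests <= 0))
    stop("invalid config: zero-size library in plan")
  .check(all(c("organ", "is_seed", "stage") %in% names(organ_panel)),
         "organ_panel is missing columns")
  .check(any(organ_panel$is_seed) && any(!organ_panel$is_seed),
         "organ panel needs at least one seed and one non-seed organ")
  .check(length(unique(organ_panel$stage[organ_panel$is_seed])) >= 2,
         "organ panel must cover at least two seed stages")
  .check(replicates_per_sample >= 1, "replicates_per_sample must be >= 1")
  .check(effect_size > 1, "effect_size must exceed 1")
  .check(seed_leak >= 0, "seed_leak must be nonnegative")
  .check(noise_sd >= 0, "noise_sd must be nonnegative")
  .check(suffix_fraction >= 0 && suffix_fraction <= 1,
         "suffix_fraction must be in [0, 1]")
  .check(no_probeset_fraction >= 0 && no_probeset_fraction < 1,
         "no_probeset_fraction must be in [0, 1)")
  .check(homology_fraction >= 0 && homology_fraction <= 1,
         "homology_fraction must be in [0, 1]")
  .check(conservation >= 0 && conservation <= 1,
         "conservation must be in [0, 1]")
  .check(go_bias >= 0 && go_bias <= 1, "go_bias must be in [0, 1]")
  .check(is.null(identity_sampler) || is.function(identity_sampler),
         "identity_sampler must be a function(n) or NULL")
  .check(identity_range[1] > 45 && identity_range[2] <= 100 &&
           identity_range[1] <= identity_range[2],
         "identity_range must lie in (45, 100]")

  cfg <- list(
    n_genes = as.integer(n_genes),
    n_seed_specific = as.integer(n_seed_specific),
    n_ddd_decoys = as.integer(n_ddd_decoys),
    n_array_decoys = as.integer(n_array_decoys),
    library_plan = library_plan,
    organ_panel = organ_panel,
    replicates_per_sample = as.integer(replicates_per_sample),
    effect_size = effect_size,
    seed_leak = seed_leak,
    noise_sd = noise_sd,
    array_floor = array_floor,
    suffix_fraction = suffix_fraction,
    no_probeset_fraction = no_probeset_fraction,
    homology_fraction = homology_fraction,
    conservation = conservation,
    identity_range = identity_range,
    identity_sampler = identity_sampler,
    go_n_terms = as.integer(go_n_terms),
    go_mean_terms = go_mean_terms,
    go_base_rate = go_base_rate,
    go_bias = go_bias,
    gene_prefix = gene_prefix,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

# tissue vocabulary: union of library tissues and array organs
.tissue_set <- function(config) {
  union(config$library_plan$tissue, config$organ_panel$organ)
}

.seed_tissue_set <- function(config) {
  union(config$library_plan$tissue[config$library_plan$pool == "A"],
        config$organ_panel$organ[config$organ_panel$is_seed])
}

#' Generate ground-truth expression profiles
#'
#' Draws, for each gene, a relative expression weight per tissue (rows sum
#' to 1) and a lognormal abundance (`mass`). Background genes are
#' tissue-flat -- identical relative weight everywhere -- so they are exact
#' nulls for the downstream pool-fraction test. Planted seed-specific genes
#' put weight on the seed tissues and only a residual `seed_leak` weight
#' elsewhere, capped so every seed weight is at least `effect_size` times
#' every non-seed weight.
#'
#' Two planted decoy classes emulate single-assay false positives: DDD
#' decoys add expression in organs only the array panel measures, array
#' decoys in tissues only the EST libraries sample.
#'
#' @param config a [synth_config()].
#' @return object of class `truth_profiles`: list with `genes`
#'   (data.frame: gene_id, is_seed_specific, role in
#'   background/planted/ddd_decoy/array_decoy, annotation_class, mass),
#'   `weights` (gene x tissue matrix, rows sum to 1), and `seed_tissues`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$rng_seed + 1L)
  n <- config$n_genes
  tissues <- .tissue_set(config)
  seed_tissues <- .seed_tissue_set(config)
  nonseed <- setdiff(tissues, seed_tissues)

  gene_id <- sprintf("%s%05d", config$gene_prefix, seq_len(n))
  role <- rep("background", n)
  n_special <- config$n_seed_specific + config$n_ddd_decoys +
    config$n_array_decoys
  if (n_special > 0) {
    idx <- sample.int(n, n_special)
    role[idx] <- rep(c("planted", "ddd_decoy", "array_decoy"),
                     c(config$n_seed_specific, config$n_ddd_decoys,
                       config$n_array_decoys))
  }
  planted <- role == "planted"
  mass <- stats::rlnorm(n, meanlog = 0, sdlog = 1)

  # tissues only one assay can see, used to plant single-assay decoys
  array_only <- setdiff(config$organ_panel$organ[!config$organ_panel$is_seed],
                        config$library_plan$tissue)
  est_only <- setdiff(
    config$library_plan$tissue[config$library_plan$pool == "B"],
    config$organ_panel$organ)
  if (config$n_ddd_decoys > 0 && !length(array_only))
    stop("n_ddd_decoys > 0 needs a non-seed organ absent from the EST libraries")
  if (config$n_array_decoys > 0 && !length(est_only))
    stop("n_array_decoys > 0 needs a non-seed EST tissue absent from the array panel")

  w <- matrix(1, nrow = n, ncol = length(tissues),
              dimnames = list(gene_id, tissues))
  leak_of <- function(ts) pmin(config$seed_leak *
                                 stats::runif(length(ts), 0.25, 1),
                               1 / config$effect_size)
  for (i in which(planted)) w[i, nonseed] <- leak_of(nonseed)
  for (i in which(role == "ddd_decoy"))       # seed + array-only organs
    w[i, setdiff(nonseed, array_only)] <- leak_of(setdiff(nonseed, array_only))
  for (i in which(role == "array_decoy"))     # seed + EST-only tissues
    w[i, setdiff(nonseed, est_only)] <- leak_of(setdiff(nonseed, est_only))
  w <- w / rowSums(w)

  # characterized (CG) gene models are more frequent among abundant genes
  u <- rank(mass, ties.method = "first") / n
  p_cg <- 0.10 + 0.35 * u
  cls <- character(n)
  for (i in seq_len(n)) {
    cls[i] <- sample(c("CG", "SG", "UG"), 1,
                     prob = c(p_cg[i],
                              (1 - p_cg[i]) * 0.56 / 0.73,
                              (1 - p_cg[i]) * 0.17 / 0.73))
  }

  out <- list(
    genes = data.frame(gene_id = gene_id,
                       is_seed_specific = planted,
                       role = role,
                       annotation_class = cls,
                       mass = mass,
                       stringsAsFactors = FALSE),
    weights = w,
    seed_tissues = seed_tissues
  )
  class(out) <- "truth_profiles"
  out
}

#' Sample an EST count table from truth profiles
#'
#' For every library, the planned number of ESTs is drawn multinomially
#' over genes with probabilities proportional to `mass * weight(tissue)`,
#' so each count column sums exactly to the library's planned total.
#'
#' @param truth a `truth_profiles` object.
#' @param config a [synth_config()]; every library tissue must appear among
#'   the truth's weight columns.
#' @return object of class `est_counts`: list with `counts` (gene x library
#'   integer matrix) and `catalog` (the library plan).
#' @export
sample_est_counts <- function(truth, config) {
  stopifnot(inherits(truth, "truth_profiles"))
  plan <- config$library_plan
  if (any(plan$n_ests <= 0)) stop("invalid config: zero-size library")
  missing <- setdiff(plan$tissue, colnames(truth$weights))
  if (length(missing))
    stop("library tissues absent from truth weights: ",
         paste(missing, collapse = ", "))
  set.seed(config$rng_seed + 2L)
  counts <- matrix(0L, nrow = nrow(truth$weights), ncol = nrow(plan),
                   dimnames = list(rownames(truth$weights), plan$library_id))
  for (j in seq_len(nrow(plan))) {
    p <- truth$genes$mass * truth$weights[, plan$tissue[j]]
    if (sum(p) <= 0) stop("all-zero sampling weights for library ",
                          plan$library_id[j])
    counts[, j] <- as.integer(stats::rmultinom(1, plan$n_ests[j], p))
  }
  out <- list(counts = counts, catalog = plan)
  class(out) <- "est_counts"
  out
}

#' Sample a replicated log2 expression matrix
#'
#' Each gene gets one clean probeset (`<gene>_at`) unless it falls in the
#' `no_probeset_fraction`; a further `suffix_fraction` of represented genes
#' get a duplicate probeset carrying one of the cross-hybridizing suffixes
#' (`_s_at`, `_x_at`, `_a_at`, `.A1`) with inflated noise. Values are
#' `log2(mass * weight(organ) + array_floor) + 12` plus Gaussian noise of
#' sd `noise_sd`, with `replicates_per_sample` columns per organ.
#'
#' @inheritParams sample_est_counts
#' @return object of class `expr_matrix`: list with `values` (probeset x
#'   sample matrix), `samples` (sample_id, organ, replicate), `organs`
#'   (the organ panel) and `probe_map` (probeset_id, gene_id).
#' @export
sample_expression_matrix <- function(truth, config) {
  stopifnot(inherits(truth, "truth_profiles"))
  panel <- config$organ_panel
  .check(nrow(panel) > 0, "organ panel must be nonempty")
  set.seed(config$rng_seed + 3L)

  genes <- truth$genes$gene_id
  n <- length(genes)
  has_probe <- stats::runif(n) >= config$no_probeset_fraction
  has_suffix <- has_probe & (stats::runif(n) < config$suffix_fraction)

  suffixes <- c("_s_at", "_x_at", "_a_at", ".A1_at")
  probe_map <- data.frame(
    probeset_id = paste0(genes[has_probe], "_at"),
    gene_id = genes[has_probe],
    stringsAsFactors = FALSE
  )
  if (any(has_suffix)) {
    sfx <- sample(suffixes, sum(has_suffix), replace = TRUE)
    probe_map <- rbind(probe_map, data.frame(
      probeset_id = paste0(genes[has_suffix], sfx),
      gene_id = genes[has_suffix],
      stringsAsFactors = FALSE
    ))
  }

  reps <- config$replicates_per_sample
  samples <- data.frame(
    sample_id = paste0("S", rep(seq_len(nrow(panel)), each = reps),
                       "_r", rep(seq_len(reps), nrow(panel))),
    organ = rep(panel$organ, each = reps),
    replicate = rep(seq_len(reps), nrow(panel)),
    stringsAsFactors = FALSE
  )

  idx <- match(probe_map$gene_id, genes)
  base <- log2(truth$genes$mass[idx] * truth$weights[idx, panel$organ,
                                                     drop = FALSE] +
                 config$array_floor) + 12
  is_sfx <- grepl("(_s_at|_x_at|_a_at)$", probe_map$probeset_id) |
    grepl(".A1", probe_map$probeset_id, fixed = TRUE)
  sd_row <- ifelse(is_sfx, 1.5 * config$noise_sd, config$noise_sd)

  values <- base[, samples$organ, drop = FALSE] +
    matrix(stats::rnorm(nrow(probe_map) * nrow(samples), sd = 1), # scaled below
           nrow = nrow(probe_map)) * sd_row
  dimnames(values) <- list(probe_map$probeset_id, samples$sample_id)

  out <- list(values = values, samples = samples, organs = panel,
              probe_map = probe_map)
  class(out) <- "expr_matrix"
  out
}

#' Sample a cross-species homology table
#'
#' About `homology_fraction` of query-species genes are paired to a
#' subject-species gene; a paired planted query maps to a planted subject
#' with probability `conservation`, otherwise (and for background queries)
#' to a background subject. Percent identity is drawn from
#' `identity_sampler` or uniformly over `identity_range`.
#'
#' @param truth_a query-species `truth_profiles`.
#' @param truth_b subject-species `truth_profiles`.
#' @param config a [synth_config()].
#' @return data.frame of class `homology_table` with columns `query`,
#'   `subject`, `pct_identity`.
#' @export
sample_homology <- function(truth_a, truth_b, config) {
  stopifnot(inherits(truth_a, "truth_profiles"),
            inherits(truth_b, "truth_profiles"))
  .check(nrow(truth_a$genes) > 0 && nrow(truth_b$genes) > 0,
         "both truth collections must be nonempty")
  set.seed(config$rng_seed + 4L)
  a <- truth_a$genes
  b <- truth_b$genes
  paired <- stats::runif(nrow(a)) < config$homology_fraction
  if (!any(paired)) {
    out <- data.frame(query = character(), subject = character(),
                      pct_identity = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("homology_table", "data.frame")
    return(out)
  }
  b_planted <- b$gene_id[b$is_seed_specific]
  b_background <- b$gene_id[!b$is_seed_specific]
  if (!length(b_background)) b_background <- b$gene_id
  pick <- function(pool) pool[sample.int(length(pool), 1)]
  subject <- vapply(which(paired), function(i) {
    if (a$is_seed_specific[i] && length(b_planted) &&
        stats::runif(1) < config$conservation) pick(b_planted)
    else pick(b_background)
  }, character(1))
  n_pairs <- sum(paired)
  identity <- if (is.function(config$identity_sampler))
    config$identity_sampler(n_pairs)
  else stats::runif(n_pairs, config$identity_range[1],
                    config$identity_range[2])
  out <- data.frame(query = a$gene_id[paired], subject = subject,
                    pct_identity = identity, stringsAsFactors = FALSE)
  class(out) <- c("homology_table", "data.frame")
  out
}

#' Sample a sparse gene-to-GO annotation table
#'
#' Every gene receives random terms from a vocabulary of `go_n_terms`
#' (mean `go_mean_terms` per gene) plus, possibly, one designated
#' seed-biased term whose annotation probability is
#' `base + bias * (1 - base)` for planted genes and `base * (1 - bias)` for
#' background genes; with `go_bias = 1` it annotates only planted genes,
#' with `go_bias = 0` both groups at the same rate.
#'
#' @inheritParams sample_est_counts
#' @return data.frame (gene_id, go_id) with attribute `seed_term` naming
#'   the biased term.
#' @export
sample_go_annotation <- function(truth, config) {
  stopifnot(inherits(truth, "truth_profiles"))
  set.seed(config$rng_seed + 5L)
  genes <- truth$genes$gene_id
  planted <- truth$genes$is_seed_specific
  terms <- sprintf("GO:%07d", seq_len(config$go_n_terms))
  seed_term <- "GO:0048316"  # seed development

  p_term <- config$go_mean_terms / config$go_n_terms
  hit <- matrix(stats::runif(length(genes) * length(terms)) < p_term,
                nrow = length(genes))
  idx <- which(hit, arr.ind = TRUE)
  ann <- data.frame(gene_id = genes[idx[, 1]], go_id = terms[idx[, 2]],
                    stringsAsFactors = FALSE)

  r <- config$go_base_rate
  p_seed <- ifelse(planted, r + config$go_bias * (1 - r),
                   r * (1 - config$go_bias))
  seeded <- stats::runif(length(genes)) < p_seed
  if (any(seeded))
    ann <- rbind(ann, data.frame(gene_id = genes[seeded], go_id = seed_term,
                                 stringsAsFactors = FALSE))
  ann <- ann[order(ann$gene_id, ann$go_id), , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "seed_term") <- seed_term
  ann
}

#' Generate a complete synthetic dataset for one species
#'
#' Convenience wrapper running [generate_truth()], [sample_est_counts()],
#' [sample_expression_matrix()] and [sample_go_annotation()] from one
#' config.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_data` with elements `truth`, `est`,
#'   `expr`, `go` and `config`.
#' @export
synth_dataset <- function(config) {
  truth <- generate_truth(config)
  out <- list(truth = truth,
              est = sample_est_counts(truth, config),
              expr = sample_expression_matrix(truth, config),
              go = sample_go_annotation(truth, config),
              config = config)
  class(out) <- "synth_data"
  out
}
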