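test_that("generators are deterministic given the config seed", {
  cfg <- tiny_config()
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  expect_identical(sample_est_counts(t1, cfg)$counts,
                   sample_est_counts(t2, cfg)$counts)
  e1 <- sample_expression_matrix(t1, cfg)
  e2 <- sample_expression_matrix(t1, cfg)
  expect_identical(e1$values, e2$values)
  expect_identical(e1$probe_map, e2$probe_map)
  cfgB <- tiny_config(gene_prefix = "Os.")
  expect_identical(sample_homology(t1, generate_truth(cfgB), cfg),
                   sample_homology(t1, generate_truth(cfgB), cfg))
  expect_identical(sample_go_annotation(t1, cfg),
                   sample_go_annotation(t1, cfg))
})

test_that("truth profiles honor the planted-gene contract", {
  cfg <- tiny_config(n_genes = 500, n_seed_specific = 25, effect_size = 8)
  truth <- generate_truth(cfg)
  expect_equal(sum(truth$genes$is_seed_specific), 25)
  expect_equal(unname(rowSums(truth$weights)), rep(1, 500), tolerance = 1e-9)
  seed_t <- truth$seed_tissues
  non_t <- setdiff(colnames(truth$weights), seed_t)
  for (i in which(truth$genes$is_seed_specific)) {
    w <- truth$weights[i, ]
    # every seed weight at least effect_size times every non-seed weight,
    # and seed share at least effect_size times the mean non-seed share
    expect_gte(min(w[seed_t]), cfg$effect_size * max(w[non_t]))
    expect_gte(min(w[seed_t]), cfg$effect_size * mean(w[non_t]))
  }
  # no flagged genes when none are requested
  none <- generate_truth(tiny_config(n_seed_specific = 0))
  expect_false(any(none$genes$is_seed_specific))
  expect_error(synth_config(n_genes = 10, n_seed_specific = 11),
               "exceeds")
})

test_that("EST sampling conserves library totals and respects zero weights", {
  cfg <- tiny_config()
  truth <- generate_truth(cfg)
  est <- sample_est_counts(truth, cfg)
  expect_identical(unname(colSums(est$counts)),
                   as.double(cfg$library_plan$n_ests))
  expect_true(all(est$counts >= 0))

  # a gene with zero weight in every pool-B tissue draws no pool-B ESTs
  w <- matrix(1, nrow = 3, ncol = 5,
              dimnames = list(paste0("g", 1:3),
                              c("seed", "grain", "leaf", "root", "spike")))
  w[1, c("leaf", "root", "spike")] <- 0
  est0 <- sample_est_counts(make_truth(w), cfg)
  b_cols <- cfg$library_plan$library_id[cfg$library_plan$pool == "B"]
  expect_identical(sum(est0$counts["g1", b_cols]), 0L)

  bad <- cfg
  bad$library_plan$n_ests[1] <- 0L
  expect_error(sample_est_counts(truth, bad), "zero-size")
})

test_that("expression matrices have exact replicate structure", {
  cfg0 <- tiny_config(noise_sd = 0)
  truth <- generate_truth(cfg0)
  expr <- sample_expression_matrix(truth, cfg0)
  # noiseless replicates of an organ are identical
  for (org in cfg0$organ_panel$organ) {
    cols <- expr$samples$sample_id[expr$samples$organ == org]
    expect_true(all(expr$values[, cols] == expr$values[, cols[1]]))
  }
  # planted genes exceed the effect size on the linear scale, noiselessly
  om <- collapse_replicates(expr)
  planted_probes <- paste0(
    truth$genes$gene_id[truth$genes$is_seed_specific], "_at")
  planted_probes <- intersect(planted_probes, rownames(om$values))
  lin <- 2^om$values
  seed_cols <- cfg0$organ_panel$organ[cfg0$organ_panel$is_seed]
  other_cols <- setdiff(cfg0$organ_panel$organ, seed_cols)
  for (p in planted_probes) {
    expect_gte(max(lin[p, seed_cols]) / max(lin[p, other_cols]),
               cfg0$effect_size)
  }
  # the suffixed-probeset draw is reproducible
  cfg <- tiny_config(n_genes = 100, suffix_fraction = 0.2,
                     no_probeset_fraction = 0)
  t2 <- generate_truth(cfg)
  n_sfx <- function() {
    m <- sample_expression_matrix(t2, cfg)$probe_map
    sum(grepl("(_s_at|_x_at|_a_at)$", m$probeset_id) |
          grepl(".A1", m$probeset_id, fixed = TRUE))
  }
  n1 <- n_sfx()
  expect_gt(n1, 0)
  expect_identical(n1, n_sfx())
})

test_that("homology sampling obeys fraction, conservation and identity bounds", {
  cfgA <- tiny_config(homology_fraction = 1, conservation = 1)
  cfgB <- tiny_config(gene_prefix = "Os.", rng_seed = 43L)
  ta <- generate_truth(cfgA)
  tb <- generate_truth(cfgB)
  hom <- sample_homology(ta, tb, cfgA)
  expect_equal(nrow(hom), cfgA$n_genes)
  planted_a <- ta$genes$gene_id[ta$genes$is_seed_specific]
  planted_b <- tb$genes$gene_id[tb$genes$is_seed_specific]
  expect_true(all(hom$subject[hom$query %in% planted_a] %in% planted_b))
  expect_true(all(hom$pct_identity > 45 & hom$pct_identity <= 100))

  none <- sample_homology(ta, tb, tiny_config(homology_fraction = 0))
  expect_equal(nrow(none), 0)
})

test_that("GO annotation bias behaves at its extremes", {
  cfg1 <- tiny_config(n_genes = 300, n_seed_specific = 30, go_bias = 1)
  t1 <- generate_truth(cfg1)
  ann1 <- sample_go_annotation(t1, cfg1)
  seed_term <- attr(ann1, "seed_term")
  carriers <- ann1$gene_id[ann1$go_id == seed_term]
  planted <- t1$genes$gene_id[t1$genes$is_seed_specific]
  expect_true(all(carriers %in% planted))
  expect_gt(length(carriers), 0)

  # with no bias the annotation rates of the two groups match in expectation
  rates <- sapply(1:20, function(i) {
    cfg0 <- tiny_config(n_genes = 300, n_seed_specific = 150, go_bias = 0,
                        rng_seed = 1000L + i)
    t0 <- generate_truth(cfg0)
    a0 <- sample_go_annotation(t0, cfg0)
    pl <- t0$genes$gene_id[t0$genes$is_seed_specific]
    carr <- a0$gene_id[a0$go_id == attr(a0, "seed_term")]
    c(mean(pl %in% carr), mean(setdiff(t0$genes$gene_id, pl) %in% carr))
  })
  expect_lt(abs(mean(rates[1, ]) - mean(rates[2, ])), 0.03)
})
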