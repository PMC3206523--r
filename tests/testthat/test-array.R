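test_that("the probeset filter removes exactly the flagged designs", {
  ids <- c("Ta.1_at", "Ta.2_s_at", "Ta.3_x_at", "Ta.4_a_at",
           "TaAffx.4.1.A1_at", "Ta.5.at", "Ta.s_at_like_at")
  kept <- filter_probesets(ids)
  expect_identical(kept, c("Ta.1_at", "Ta.5.at", "Ta.s_at_like_at"))
  # idempotent, preserves order, handles the empty mapping
  expect_identical(filter_probesets(kept), kept)
  expect_identical(filter_probesets(character(0)), character(0))
  # data.frame mappings are filtered by row
  map <- data.frame(probeset_id = ids, gene_id = paste0("g", 1:7),
                    stringsAsFactors = FALSE)
  expect_identical(filter_probesets(map)$gene_id, c("g1", "g6", "g7"))
})

test_that("replicate collapsing is the arithmetic log2 mean per organ", {
  panel <- data.frame(organ = c("leaf", "seed"), is_seed = c(FALSE, TRUE),
                      stage = c(NA, "22 DPA"), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("l1", "l2", "l3", "s1"),
                        organ = c("leaf", "leaf", "leaf", "seed"),
                        replicate = c(1:3, 1), stringsAsFactors = FALSE)
  values <- matrix(c(4, 6, 5, 9), nrow = 1,
                   dimnames = list("p1", samples$sample_id))
  expr <- structure(list(values = values, samples = samples, organs = panel,
                         probe_map = data.frame(probeset_id = "p1",
                                                gene_id = "g1")),
                    class = "expr_matrix")
  om <- collapse_replicates(expr)
  expect_equal(om$values["p1", "leaf"], 5)   # mean(4, 6, 5)
  expect_equal(om$values["p1", "seed"], 9)   # single replicate: identity

  bad <- expr
  bad$organs <- rbind(panel, data.frame(organ = "root", is_seed = FALSE,
                                        stage = NA))
  expect_error(collapse_replicates(bad), "zero replicate")
})

test_that("the seed-specificity call is a strict linear-scale fold rule", {
  panel <- data.frame(
    organ = c("leaf", "root", "early seed", "late seed"),
    is_seed = c(FALSE, FALSE, TRUE, TRUE),
    stage = c(NA, NA, "3-5 DPA", "22 DPA"), stringsAsFactors = FALSE)
  values <- rbind(
    flat     = c(7, 7, 7, 7),
    boundary = c(8, 7, 8, 10),    # 2^10 / 2^8 = exactly 4-fold
    above    = c(8, 7, 8, 10.1),  # 2^2.1 ~ 4.29-fold
    early    = c(3, 3, 9, 5)
  )
  colnames(values) <- panel$organ
  om <- structure(list(values = values, organs = panel),
                  class = "organ_matrix")
  calls <- seed_specific_calls(om, fold_threshold = 4)
  expect_equal(calls$fold[calls$probeset_id == "flat"], 1)
  expect_false(calls$specific[calls$probeset_id == "flat"])
  expect_equal(calls$fold[calls$probeset_id == "boundary"], 4)
  expect_false(calls$specific[calls$probeset_id == "boundary"])
  expect_true(calls$specific[calls$probeset_id == "above"])
  expect_equal(calls$fold[calls$probeset_id == "above"], 2^2.1)
  expect_identical(calls$stage[calls$probeset_id == "above"], "22 DPA")
  expect_identical(calls$stage[calls$probeset_id == "early"], "3-5 DPA")

  # fold depends only on log2 differences: shifting one row is neutral
  om2 <- om
  om2$values["above", ] <- om2$values["above", ] + 3.7
  calls2 <- seed_specific_calls(om2, fold_threshold = 4)
  expect_equal(calls2$fold[calls2$probeset_id == "above"],
               calls$fold[calls$probeset_id == "above"])

  bad <- om
  bad$organs$is_seed <- FALSE
  expect_error(seed_specific_calls(bad), "seed")
})

test_that("pearson_r matches the direct formula and rejects degenerate input", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), direct, tolerance = 1e-12)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(2, 4)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("profile_neighbors equals the brute-force all-pairs search", {
  set.seed(31)
  values <- matrix(rnorm(20 * 6), nrow = 20,
                   dimnames = list(paste0("p", 1:20), paste0("o", 1:6)))
  values["p2", ] <- values["p1", ]               # exact duplicate of a seed
  values["p3", ] <- -values["p1", ]              # anti-correlated
  panel <- data.frame(organ = paste0("o", 1:6),
                      is_seed = c(rep(FALSE, 5), TRUE),
                      stage = c(rep(NA, 5), "22 DPA"))
  om <- structure(list(values = values, organs = panel),
                  class = "organ_matrix")
  seeds <- c("p1", "p5")
  got <- profile_neighbors(om, seeds, min_r = 0.8)
  expect_identical(sort(got), sort(oracle_neighbors(values, seeds, 0.8)))
  expect_true("p2" %in% got)
  expect_false("p3" %in% got)
  # min_r ~ 1 keeps only exact duplicates; empty seed set is empty, not an error
  expect_identical(profile_neighbors(om, seeds, min_r = 1 - 1e-9), "p2")
  expect_identical(profile_neighbors(om, character(0)), character(0))
  # min_r = -1 returns every other probeset
  expect_setequal(profile_neighbors(om, seeds, min_r = -1),
                  setdiff(rownames(values), seeds))
})

test_that("hierarchical clustering matches a naive average-linkage oracle", {
  set.seed(41)
  values <- matrix(rnorm(6 * 8), nrow = 6,
                   dimnames = list(paste0("p", 1:6), paste0("o", 1:8)))
  values["p4", ] <- values["p2", ]  # identical pair
  hc <- hierarchical_cluster(values)
  # identical rows merge first at height 0 and sit on adjacent leaves
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_equal(abs(diff(match(c("p2", "p4"), hc$order))), 1)
  # cophenetic distances agree with the O(n^3) oracle
  d <- 1 - cor(t(values))
  coph <- as.matrix(stats::cophenetic(hc$hclust))
  oracle <- oracle_average_linkage_cophenetic(d)
  dimnames(oracle) <- dimnames(coph)
  expect_equal(coph, oracle, tolerance = 1e-10)

  values["p1", ] <- 1
  expect_error(hierarchical_cluster(values), "constant")
  expect_error(hierarchical_cluster(values[1, , drop = FALSE]), ">= 2")
})

test_that("noiseless array screen recovers exactly the planted genes", {
  cfg <- tiny_config(noise_sd = 0, no_probeset_fraction = 0,
                     effect_size = 8)
  truth <- generate_truth(cfg)
  expr <- sample_expression_matrix(truth, cfg)
  scr <- array_screen(expr, fold_threshold = 4)
  called <- unique(scr$calls$unigene_id[scr$calls$specific])
  planted <- truth$genes$gene_id[truth$genes$is_seed_specific]
  expect_setequal(called, planted)
})
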