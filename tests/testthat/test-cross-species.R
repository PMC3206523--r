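test_that("similarity bins follow the strict >90 / >70 / >45 boundaries", {
  expect_identical(bin_similarity(c(92, 90, 70, 46, 45)),
                   c("HS", "MS", "WS", "WS", "none"))
  expect_identical(bin_similarity(90.0001), "HS")
  expect_error(bin_similarity(0), "identity")
  expect_error(bin_similarity(101), "identity")
})

test_that("replicated_set equals an exhaustive pair scan", {
  set.seed(61)
  list_a <- paste0("a", 1:10)
  list_b <- paste0("b", 1:6)
  hom <- data.frame(
    query = sample(paste0("a", 1:12), 20, replace = TRUE),
    subject = sample(paste0("b", 1:9), 20, replace = TRUE),
    pct_identity = runif(20, 30, 100),
    stringsAsFactors = FALSE
  )
  got <- replicated_set(list_a, hom, list_b)
  manual <- character(0)
  for (g in list_a) {
    for (r in seq_len(nrow(hom))) {
      if (hom$query[r] == g && hom$pct_identity[r] > 45 &&
          hom$subject[r] %in% list_b) { manual <- c(manual, g); break }
    }
  }
  expect_identical(sort(unique(got)), sort(manual))
  # trivial cases
  expect_identical(replicated_set(list_a, hom[0, ], list_b), character(0))
  full <- data.frame(query = list_a, subject = rep(list_b, length.out = 10),
                     pct_identity = 80)
  expect_identical(replicated_set(list_a, full, list_b), list_a)
  # identity at or below 45 never links
  weak <- data.frame(query = "a1", subject = "b1", pct_identity = 45)
  expect_identical(replicated_set("a1", weak, "b1"), character(0))
})

test_that("specificity/sensitivity are dual and truncated to one decimal", {
  list_a <- paste0("a", 1:201)
  list_b <- paste0("b", 1:70)
  hom <- rbind(
    data.frame(query = paste0("a", 1:23), subject = paste0("b", 1:23),
               pct_identity = 80),
    data.frame(query = "a1", subject = paste0("b", 24:27),
               pct_identity = 80)
  )
  s <- specificity_sensitivity(list_a, list_b, hom)
  expect_equal(s$n_replicated_a, 23)
  expect_equal(s$n_replicated_b, 27)
  expect_equal(s$specificity_1dp, 11.4)
  expect_equal(s$sensitivity_1dp, 38.5)
  expect_equal(s$specificity, 100 * 23 / 201)

  # duality: spec(a, b) = sens(b, a) under table inversion
  inv <- data.frame(query = hom$subject, subject = hom$query,
                    pct_identity = hom$pct_identity)
  s_inv <- specificity_sensitivity(list_b, list_a, inv)
  expect_equal(s_inv$sensitivity, s$specificity)
  expect_equal(s_inv$specificity, s$sensitivity)

  # fully replicated list reaches 100.0; empty lists are an error
  s_full <- specificity_sensitivity("a1", "b1",
                                    data.frame(query = "a1", subject = "b1",
                                               pct_identity = 95))
  expect_equal(s_full$specificity_1dp, 100)
  expect_error(specificity_sensitivity(character(0), list_b, hom), "empty")
})

test_that("adding a homolog pair never decreases either metric", {
  set.seed(62)
  list_a <- paste0("a", 1:15)
  list_b <- paste0("b", 1:15)
  hom <- data.frame(query = sample(list_a, 10, replace = TRUE),
                    subject = sample(list_b, 10, replace = TRUE),
                    pct_identity = runif(10, 50, 100))
  s0 <- specificity_sensitivity(list_a, list_b, hom)
  for (i in 1:10) {
    hom <- rbind(hom, data.frame(query = sample(list_a, 1),
                                 subject = sample(list_b, 1),
                                 pct_identity = runif(1, 50, 100)))
    s1 <- specificity_sensitivity(list_a, list_b, hom)
    expect_gte(s1$specificity, s0$specificity)
    expect_gte(s1$sensitivity, s0$sensitivity)
    s0 <- s1
  }
})

test_that("replication_by_bin counts counterpart gene models per bin", {
  # 13 HS, 48 MS, 37 WS counterpart models; 9/31/23 replicate
  mk <- function(prefix, n, ident) {
    data.frame(query = paste0(prefix, "_q", 1:n),
               subject = paste0(prefix, "_s", 1:n),
               pct_identity = ident, stringsAsFactors = FALSE)
  }
  hom <- rbind(mk("hs", 13, 95), mk("ms", 48, 80), mk("ws", 37, 60),
               mk("unmeasured", 8, 80))
  list_a <- hom$query
  list_b <- c(paste0("hs_s", 1:9), paste0("ms_s", 1:31), paste0("ws_s", 1:23))
  measured <- hom$subject[!grepl("unmeasured", hom$subject)]
  bb <- replication_by_bin(list_a, hom, list_b, measured = measured)
  expect_identical(bb$n, c(13L, 48L, 37L))
  expect_identical(bb$n_replicated, c(9L, 31L, 23L))
  expect_identical(bb$pct, c(69, 65, 62))
  # an empty bin reports NA, not zero
  bb2 <- replication_by_bin("hs_q1", hom[1, ], "hs_s1")
  expect_true(is.na(bb2$pct[bb2$bin == "MS"]))
  expect_identical(bb2$pct[bb2$bin == "HS"], 100)
})
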