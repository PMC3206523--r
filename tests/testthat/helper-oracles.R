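# Independent oracles, all written from first principles with lchoose so
# they share no code path with the implementation.

# two-sided Fisher exact p by exhaustive enumeration over the support of
# the 2x2 table [[a, A-a], [b, B-b]] with margins (a+b, A, B)
oracle_fisher_p <- function(a, A, b, B) {
  m <- a + b
  if (m == 0 || m == A + B) return(1)
  x <- max(0, m - B):min(m, A)
  logp <- lchoose(A, x) + lchoose(B, m - x) - lchoose(A + B, m)
  p <- exp(logp)
  pobs <- exp(lchoose(A, a) + lchoose(B, m - a) - lchoose(A + B, m))
  min(1, sum(p[p <= pobs * (1 + 1e-12)]))
}

# upper-tail hypergeometric P(X >= k) by term-by-term PMF summation
oracle_hyper_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# naive O(n^3) average-linkage agglomeration on a distance matrix;
# returns the cophenetic distance matrix (merge-order independent)
oracle_average_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_h
    coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# brute-force all-pairs profile-neighbor search
oracle_neighbors <- function(values, seed_ids, min_r) {
  others <- setdiff(rownames(values), seed_ids)
  hits <- character(0)
  for (o in others) {
    for (s in seed_ids) {
      if (sd(values[o, ]) == 0 || sd(values[s, ]) == 0) next
      if (cor(values[o, ], values[s, ]) >= min_r) { hits <- c(hits, o); break }
    }
  }
  hits
}

# small, fast generator configuration for unit tests
tiny_config <- function(...) {
  plan <- data.frame(
    library_id = paste0("L", 1:5),
    tissue = c("seed", "grain", "leaf", "root", "spike"),
    pool = c("A", "A", "B", "B", "B"),
    n_ests = c(8000L, 6000L, 9000L, 12000L, 7000L),
    stringsAsFactors = FALSE
  )
  panel <- data.frame(
    organ = c("root", "leaf", "spike", "early seed", "late seed"),
    is_seed = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stage = c(NA, NA, NA, "3-5 DPA", "22 DPA"),
    stringsAsFactors = FALSE
  )
  args <- utils::modifyList(
    list(n_genes = 60, n_seed_specific = 6, library_plan = plan,
         organ_panel = panel, rng_seed = 42L,
         # the tiny plan/panel share all non-seed tissues, so the
         # single-assay decoy classes cannot exist here
         n_ddd_decoys = 0, n_array_decoys = 0),
    list(...)
  )
  do.call(synth_config, args)
}

# hand-built truth object for fully controlled generator inputs
make_truth <- function(weights, planted = rep(FALSE, nrow(weights)),
                       mass = rep(1, nrow(weights)),
                       class = rep("SG", nrow(weights))) {
  structure(list(
    genes = data.frame(gene_id = rownames(weights),
                       is_seed_specific = planted,
                       annotation_class = class, mass = mass,
                       stringsAsFactors = FALSE),
    weights = weights / rowSums(weights),
    seed_tissues = character(0)
  ), class = "truth_profiles")
}
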