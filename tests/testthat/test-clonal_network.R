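test_that("edit distance reproduces classic cases", {
  expect_equal(cdr3_levenshtein("kitten", "sitting"), 3L)
  expect_equal(cdr3_levenshtein("CASSF", "CASSF"), 0L)
  expect_equal(cdr3_levenshtein("CASSF", ""), 5L)
  expect_equal(cdr3_levenshtein("", ""), 0L)
})

test_that("edit distance equals the recursive oracle on short strings", {
  strings <- c("")
  for (l in 1:3)
    strings <- c(strings,
                 apply(expand.grid(rep(list(c("A", "C", "G")), l)), 1,
                       paste, collapse = ""))
  set.seed(71)
  pick <- sample(length(strings)^2, 400)
  ij <- arrayInd(pick, c(length(strings), length(strings)))
  for (r in seq_len(nrow(ij))) {
    a <- strings[ij[r, 1]]; b <- strings[ij[r, 2]]
    expect_equal(cdr3_levenshtein(a, b), lev_oracle(a, b))
  }
})

test_that("similarity normalizes by the longer sequence", {
  expect_equal(cdr3_similarity(strrep("A", 14), strrep("A", 14)), 1)
  a <- paste0(strrep("A", 13), "G")
  expect_equal(cdr3_similarity(strrep("A", 14), a), 1 - 1 / 14)
  b <- paste0("GG", strrep("A", 8))
  expect_equal(cdr3_similarity(strrep("A", 10), b), 0.8)
  expect_equal(cdr3_similarity("", ""), 1)
})

test_that("clustering collapses duplicates and links by connectivity", {
  cl <- data.frame(cdr3 = rep("CASSF", 4), size = 1,
                   condition = c("pre_GFD", "pre_GFD", "post_GFD",
                                 "post_GFD"), stringsAsFactors = FALSE)
  g <- cluster_clones(cl)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(g$nodes$status, "shared")
  expect_equal(g$nodes$size, 4)
  # two dissimilar sequences stay apart
  g2 <- cluster_clones(data.frame(cdr3 = c("CASSLGQAYEQYF", "CILRDSSGGYQKF"),
                                  size = 1, condition = "pre_GFD"))
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(length(unique(g2$nodes$cluster)), 2L)
  # A-B similar, B-C similar, A-C not: one component of three
  a <- "CASSLGQAYEQYFAA"
  b <- "CASSLGQAYEQYFAG"   # 1 sub from a
  cs <- "CASSLGQAYEQYGAGG"  # close to b, farther from a
  g3 <- cluster_clones(data.frame(cdr3 = c(a, b, cs), size = 1,
                                  condition = "pre_GFD"), threshold = 0.87)
  expect_gte(cdr3_similarity(a, b), 0.87)
  expect_gte(cdr3_similarity(b, cs), 0.87)
  expect_lt(cdr3_similarity(a, cs), 0.87)
  expect_equal(length(unique(g3$nodes$cluster)), 1L)
  expect_equal(nrow(g3$edges), 2L)
})

test_that("components are invariant to input order", {
  set.seed(73)
  base <- c("CASSLGQAYEQYF", "CASSLGQAYEQYG", "CASSLGQAYEQFF",
            "CILRDSSGGYQKF", "CILRDSSGGYQKW", "CAVRDMEYGNKLVF")
  cl <- data.frame(cdr3 = base, size = seq_along(base),
                   condition = rep(c("pre_GFD", "post_GFD"), 3),
                   stringsAsFactors = FALSE)
  ref <- cluster_clones(cl)
  for (i in 1:5) {
    perm <- sample(nrow(cl))
    alt <- cluster_clones(cl[perm, ])
    expect_identical(alt$nodes, ref$nodes)
    expect_identical(alt$edges, ref$edges)
  }
})

test_that("clusters coarsen monotonically as the threshold drops", {
  set.seed(79)
  coh <- simulate_cohort(sim_config(n_patients = 1,
                                    cells_per_sample = 150, seed = 37))
  cl <- coh$truth$clones
  cl <- data.frame(cdr3 = cl$tra_cdr3_aa, size = cl$size,
                   condition = cl$condition, stringsAsFactors = FALSE)
  counts <- sapply(c(1, 0.85, 0.5, 0.2), function(th)
    length(unique(cluster_clones(cl, threshold = th)$nodes$cluster)))
  expect_true(all(diff(counts) <= 0))
  # at threshold 1, components are exact-sequence groups
  g1 <- cluster_clones(cl, threshold = 1)
  expect_equal(length(unique(g1$nodes$cluster)), nrow(g1$nodes))
  # at a very low threshold everything merges (same length support)
  g0 <- cluster_clones(cl, threshold = 1e-6)
  expect_equal(length(unique(g0$nodes$cluster)), 1L)
})

test_that("the length-difference prefilter changes nothing", {
  set.seed(83)
  coh <- simulate_cohort(sim_config(n_patients = 1,
                                    cells_per_sample = 120, seed = 41))
  u <- unique(coh$truth$clones$tra_cdr3_aa)
  th <- 0.85
  fast <- pairedTCR:::.similarity_edges(sort(u), th)
  # brute force over all pairs
  us <- sort(u)
  D <- utils::adist(us, us)
  mx <- outer(nchar(us), nchar(us), pmax)
  sim <- 1 - D / mx
  hit <- which(sim >= th & upper.tri(sim), arr.ind = TRUE)
  expect_equal(nrow(fast), nrow(hit))
  if (nrow(hit) > 0) {
    o <- order(hit[, 1], hit[, 2])
    expect_equal(fast$from_idx, hit[o, 1])
    expect_equal(fast$to_idx, hit[o, 2])
  }
})

test_that("export and re-import reconstruct an isomorphic graph", {
  cl <- data.frame(cdr3 = c("CASSLGQAYEQYF", "CASSLGQAYEQYG",
                            "CILRDSSGGYQKF"),
                   size = c(3, 1, 2),
                   condition = c("pre_GFD", "post_GFD", "pre_GFD"),
                   stringsAsFactors = FALSE)
  g <- cluster_clones(cl)
  ep <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".tsv")
  export_network(g, ep, np)
  g2 <- import_network(ep, np, threshold = g$threshold, chain = g$chain)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges[, c("from", "to")], g$edges[, c("from", "to")])
  # empty graph still yields two valid tables with headers
  ge <- cluster_clones(cl[0, ])
  export_network(ge, ep, np)
  expect_equal(nrow(utils::read.delim(ep)), 0L)
  expect_equal(nrow(utils::read.delim(np)), 0L)
})
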