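test_that("identical seeds give byte-identical cohorts", {
  a <- simulate_cohort(sim_config(n_patients = 2, cells_per_sample = 200,
                                  seed = 7))
  b <- simulate_cohort(sim_config(n_patients = 2, cells_per_sample = 200,
                                  seed = 7))
  expect_identical(a$samples, b$samples)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  d <- simulate_cohort(sim_config(n_patients = 2, cells_per_sample = 200,
                                  seed = 8))
  expect_false(identical(a$samples, d$samples))
})

test_that("emitted cell totals match the configured per-patient sizes exactly", {
  sizes <- c(3489L, 2062L, 2150L, 2534L, 1573L)
  coh <- simulate_cohort(sim_config(cells_per_sample = sizes, seed = 3))
  cl <- coh$truth$clones
  for (cond in c("pre_GFD", "post_GFD")) {
    per_pat <- tapply(cl$size[cl$condition == cond],
                      cl$patient[cl$condition == cond], sum)
    expect_equal(as.vector(per_pat[sprintf("PT%02d", 1:5)]), sizes)
  }
  # every emitted sample has exactly its configured number of cells
  for (nm in names(coh$samples))
    expect_equal(length(unique(coh$samples[[nm]]$cell_id)),
                 unname(coh$truth$cells_per_sample[sub("_(pre|post)_GFD$",
                                                       "", nm)]))
})

test_that("the null configuration reproduces pre clone-size multisets post", {
  cfg <- sim_config(n_patients = 2, cells_per_sample = 400,
                    contraction_factor = 1, persistence_prob = 1,
                    pairing_effects = NULL, seed = 11)
  coh <- simulate_cohort(cfg)
  cl <- coh$truth$clones
  for (p in unique(cl$patient)) {
    pre <- sort(cl$size[cl$patient == p & cl$condition == "pre_GFD"])
    post <- sort(cl$size[cl$patient == p & cl$condition == "post_GFD"])
    expect_identical(pre, post)
  }
  expect_true(all(cl$fate %in% c("persisting", "lost")))
})

test_that("no clone exceeds 100 cells under the default configuration", {
  coh <- simulate_cohort(sim_config(seed = 5))
  expect_lte(max(coh$truth$clones$size), 100L)
})

test_that("infeasible expanded sizes are rejected before sampling", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 50,
                    expanded_size_range = c(60, 100), seed = 1)
  expect_error(simulate_cohort(cfg), "infeasible")
})

test_that("CDR3s carry the canonical C/F anchors and lengths in support", {
  coh <- simulate_cohort(sim_config(n_patients = 1, cells_per_sample = 300,
                                    seed = 9))
  cl <- coh$truth$clones
  for (col in c("tra_cdr3_aa", "trb_cdr3_aa")) {
    expect_true(all(startsWith(cl[[col]], "C")))
    expect_true(all(endsWith(cl[[col]], "F")))
    expect_true(all(nchar(cl[[col]]) >= 8 & nchar(cl[[col]]) <= 20))
    # nucleotide junctions are in-frame back-translations
    nt <- cl[[sub("aa", "nt", col)]]
    expect_equal(nchar(nt), 3L * nchar(cl[[col]]))
  }
})

test_that("with no pairing effects, pair frequencies follow the usage product", {
  # singleton clones so clone draws are iid from the joint distribution
  cfg <- pairing_cohort_config(seed = 21)
  cfg$cells_per_sample <- 5000L
  coh <- simulate_cohort(cfg)
  cl <- coh$truth$clones
  cl <- cl[cl$condition == "pre_GFD", ]
  obs <- table(factor(cl$trav, levels = cfg$trav_pool),
               factor(cl$trbv, levels = cfg$trbv_pool))
  pA <- rowSums(obs) / sum(obs)
  pB <- colSums(obs) / sum(obs)
  expected <- outer(pA, pB) * sum(obs)
  stat <- sum((obs - expected)^2 / expected)
  # df for independence on the observed margins
  p <- pchisq(stat, (length(pA) - 1) * (length(pB) - 1),
              lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("ground truth report books effects and per-patient contrasts", {
  eff <- data.frame(trav = "TRAV2", trbv = "TRBV6-2", log_odds = log(8),
                    condition = "pre_GFD", stringsAsFactors = FALSE)
  coh <- simulate_cohort(sim_config(n_patients = 2, cells_per_sample = 300,
                                    pairing_effects = eff, seed = 13))
  rep <- ground_truth_report(coh$truth)
  expect_equal(sum(rep$kind == "pairing_log_odds"), 1L)
  expect_equal(rep$true_value[rep$kind == "pairing_log_odds"], log(8))
  expect_equal(sum(rep$kind == "unique_clone_fraction_delta"), 2L)
  # null cohort: no nonzero effect rows
  coh0 <- simulate_cohort(sim_config(n_patients = 2,
                                     cells_per_sample = 300,
                                     pairing_effects = NULL, seed = 13))
  rep0 <- ground_truth_report(coh0$truth)
  expect_equal(sum(rep0$kind == "pairing_log_odds"), 0L)
})

test_that("contraction with partial persistence raises the unique-clone fraction", {
  coh <- simulate_cohort(sim_config(n_patients = 3,
                                    cells_per_sample = 800, seed = 17))
  uf <- coh$truth$unique_clone_fraction
  wide <- merge(uf[uf$condition == "pre_GFD", c("patient",
                                                "unique_clone_fraction")],
                uf[uf$condition == "post_GFD", c("patient",
                                                 "unique_clone_fraction")],
                by = "patient")
  expect_true(all(wide[[3]] > wide[[2]]))
})

test_that("cohorts written to disk round-trip through the reader", {
  dir <- tempfile()
  coh <- simulate_cohort(sim_config(n_patients = 1,
                                    cells_per_sample = 150, seed = 23),
                         dir = dir)
  f <- list.files(dir)
  expect_true("cell_metadata.tsv" %in% f)
  expect_true("sim_truth.json" %in% f)
  expect_true(any(grepl("_contigs\\.tsv$", f)))
  rec <- read_contigs(file.path(dir, "PT01_pre_GFD_contigs.tsv"),
                      "airr_tsv")
  expect_equal(length(unique(rec$barcode)), 150L)
})
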