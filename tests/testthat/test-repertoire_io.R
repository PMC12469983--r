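airr_path <- system.file("extdata", "example_contigs_airr.tsv",
                         package = "pairedTCR")
tenx_path <- system.file("extdata", "example_contigs_10x.csv",
                         package = "pairedTCR")

test_that("AIRR rows map to contig records with alleles stripped and non-productive dropped", {
  rec <- read_contigs(airr_path, "airr_tsv")
  expect_false(any(grepl("\\*", rec$v_call)))
  r1 <- rec[rec$barcode == "AAACCTGAGAAACGAG-1" & rec$locus == "TRA", ]
  expect_equal(r1$v_call, "TRAV10")
  expect_equal(r1$cdr3_aa, "CVVSDNTGGFKTIF")
  expect_equal(r1$umis, 4L)
  # the productive=FALSE TRBV6-2 row is excluded
  expect_false("TRBV6-2" %in% rec$v_call)
  expect_true(all(rec$productive))
})

test_that("10x dialect drops non-cell / low-confidence rows", {
  rec <- read_contigs(tenx_path, "tenx_csv")
  # the is_cell=FALSE TRA contig of AAACGGGCAGTTCGTA-1 is excluded
  expect_false(any(rec$barcode == "AAACGGGCAGTTCGTA-1" & rec$locus == "TRA"))
  expect_equal(sort(unique(rec$locus)), c("TRA", "TRB"))
  expect_false(any(grepl("\\*", rec$v_call)))
})

test_that("missing mandatory columns are reported by name", {
  tf <- tempfile(fileext = ".tsv")
  writeLines("cell_id\tlocus\tv_call", tf)
  expect_error(read_contigs(tf, "airr_tsv"), "junction")
})

test_that("an empty file with a valid header yields an empty record set", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(paste(c("cell_id", "locus", "v_call", "j_call", "c_call",
                     "junction", "junction_aa", "duplicate_count",
                     "productive"), collapse = "\t"), tf)
  rec <- read_contigs(tf, "airr_tsv")
  expect_equal(nrow(rec), 0L)
})

test_that("rows with invalid CDR3 alphabet are rejected and counted", {
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(cell_id = c("a-1", "b-1"), locus = "TRA",
                   v_call = "TRAV2", j_call = "TRAJ4", c_call = "TRAC",
                   junction = "TGT", junction_aa = c("CAF", "CXZ#"),
                   duplicate_count = 1, productive = "TRUE")
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(rec <- read_contigs(tf, "airr_tsv"), "rejected")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "rejected_rows"), 1L)
})

test_that("barcode standardization prefixes once and is idempotent", {
  rec <- contig_row("AAAC-1", "TRA", "TRAV10")
  out <- standardize_barcodes(rec, "CEL_01_pre")
  expect_equal(out$barcode, "CEL_01_pre_AAAC-1")
  expect_equal(standardize_barcodes(out, "CEL_01_pre")$barcode,
               "CEL_01_pre_AAAC-1")
  expect_error(standardize_barcodes(rec, ""), "non-empty")
  # consistency: shared barcodes share the prefixed id
  three <- do.call(rbind, replicate(3, rec, simplify = FALSE))
  expect_length(unique(standardize_barcodes(three, "S")$barcode), 1L)
})

test_that("filter_chains keeps the max-UMI chain per locus and requires both loci", {
  rec <- rbind(contig_row("b1", "TRA", "TRAV10", umis = 5, cdr3_nt = "AAA"),
               contig_row("b1", "TRA", "TRAV2", umis = 2, cdr3_nt = "CCC"),
               contig_row("b1", "TRB", "TRBV28", umis = 7),
               contig_row("b2", "TRB", "TRBV14", umis = 3))
  cells <- filter_chains(rec)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$tra_v, "TRAV10")
  expect_equal(cells$tra_umis, 5L)
  expect_equal(cells$trb_umis, 7L)
  log <- attr(cells, "filter_log")
  expect_equal(log$no_tra, 1L)           # b2 lacks a TRA
  expect_equal(log$extra_chains_dropped, 1L)
})

test_that("UMI ties break on lexicographically smallest cdr3_nt, independent of order", {
  rec <- rbind(contig_row("b1", "TRA", "TRAV10", umis = 4, cdr3_nt = "TTT"),
               contig_row("b1", "TRA", "TRAV2", umis = 4, cdr3_nt = "AAA"),
               contig_row("b1", "TRB", "TRBV28", umis = 2))
  ref <- filter_chains(rec)
  expect_equal(ref$tra_cdr3_nt, "AAA")
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(3, 1, 2))) {
    alt <- filter_chains(rec[perm, ])
    expect_identical(alt, ref, ignore_attr = TRUE)
  }
})

test_that("metadata join drops unmatched cells and refuses duplicate ids", {
  cells <- make_cells(5)
  meta <- data.frame(cell_id = cells$cell_id[1:4], patient = "PT01",
                     condition = "pre_GFD", subset = "CD4",
                     stringsAsFactors = FALSE)
  out <- attach_metadata(cells[, 1:13], meta)
  expect_equal(nrow(out), 4L)
  expect_equal(attr(out, "dropped_cells"), 1L)
  expect_error(attach_metadata(cells[, 1:13], rbind(meta, meta[1, ])),
               "duplicate")
  # disjoint sets: empty result plus warning
  meta2 <- transform(meta, cell_id = paste0("other_", cell_id))
  expect_warning(out2 <- attach_metadata(cells[, 1:13], meta2), "no cells")
  expect_equal(nrow(out2), 0L)
})

test_that("2 patients x 2 conditions in metadata give 4 sample groups", {
  cells <- make_cells(8)
  meta <- data.frame(cell_id = cells$cell_id,
                     patient = rep(c("PT01", "PT02"), each = 4),
                     condition = rep(c("pre_GFD", "post_GFD"), 4),
                     subset = "CD4", stringsAsFactors = FALSE)
  out <- attach_metadata(cells[, 1:13], meta)
  expect_length(unique(out$sample), 4L)
})

test_that("AIRR write / read / filter round trip reproduces the cell records", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 120, seed = 42)
  cells <- cohort_cells(simulate_cohort(cfg))
  tf <- tempfile(fileext = ".tsv")
  write_airr(cells, tf)
  back <- filter_chains(read_contigs(tf, "airr_tsv"))
  chain_cols <- setdiff(names(back), "cell_id")
  expect_equal(back$cell_id, sort(cells$cell_id))
  m <- match(back$cell_id, cells$cell_id)
  for (col in chain_cols) expect_equal(back[[col]], cells[[col]][m])
})
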