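# Small in-code fixtures shared across test files.

# One contig row in the internal contig data.frame layout.
contig_row <- function(barcode, locus, v, cdr3_nt = "TGTGCC",
                       cdr3_aa = "CAF", umis = 1L, productive = TRUE,
                       j = NULL, cc = NULL) {
  if (is.null(j)) j <- if (locus == "TRA") "TRAJ12" else "TRBJ1-1"
  if (is.null(cc)) cc <- if (locus == "TRA") "TRAC" else "TRBC1"
  data.frame(barcode = barcode, locus = locus, v_call = v, j_call = j,
             c_call = cc, cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
             umis = as.integer(umis), productive = productive,
             stringsAsFactors = FALSE)
}

# A minimal paired-cell data.frame (filter_chains output layout).
make_cells <- function(n, tra_v = "TRAV10", trb_v = "TRBV28",
                       tra_cdr3_aa = "CVVSDNTGGFKTIF",
                       trb_cdr3_aa = "CASSLSYGYTF",
                       tra_cdr3_nt = NULL, trb_cdr3_nt = NULL,
                       patient = "PT01", condition = "pre_GFD",
                       subset = "CD4") {
  if (is.null(tra_cdr3_nt)) tra_cdr3_nt <- strrep("TGC", 5)
  if (is.null(trb_cdr3_nt)) trb_cdr3_nt <- strrep("GCA", 5)
  df <- data.frame(cell_id = sprintf("cell%03d", seq_len(n)),
                   tra_v = tra_v, tra_j = "TRAJ12", tra_c = "TRAC",
                   tra_cdr3_nt = tra_cdr3_nt, tra_cdr3_aa = tra_cdr3_aa,
                   tra_umis = 2L,
                   trb_v = trb_v, trb_j = "TRBJ1-1", trb_c = "TRBC1",
                   trb_cdr3_nt = trb_cdr3_nt, trb_cdr3_aa = trb_cdr3_aa,
                   trb_umis = 3L,
                   stringsAsFactors = FALSE)
  df$patient <- patient
  df$condition <- condition
  df$subset <- subset
  df$sample <- paste(df$patient, df$condition, sep = "|")
  df
}

# Cohort configuration used by the pairing-recovery checks: a reduced
# 10x10 gene panel with near-uniform usage and full clonal turnover, so
# every pair has expected count ~20 and the exact test has power.
pairing_cohort_config <- function(seed, effects = NULL) {
  sim_config(n_patients = 1, cells_per_sample = 2000,
             expanded_fraction_pre = 0, persistence_prob = 0,
             usage_concentration = 50, patient_noise = 0.01,
             trav_pool = pairedTCR:::.default_trav_pool[1:10],
             trbv_pool = pairedTCR:::.default_trbv_pool[1:10],
             pairing_effects = effects, seed = seed)
}

pairing_recovery_effects <- function() {
  data.frame(trav = c("TRAV2", "TRAV6"), trbv = c("TRBV5-1", "TRBV9"),
             log_odds = log(8), condition = c("post_GFD", "pre_GFD"),
             stringsAsFactors = FALSE)
}
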