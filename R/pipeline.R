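# End-to-end orchestration: io -> clonotypes -> diversity/overlap ->
# sequence features -> pairing -> clustering, with every stage written as a
# plain-text table and a JSON manifest whose hash certifies determinism.

#' Assemble and validate a pipeline run configuration
#'
#' Exactly one of `simulate` (arguments for [sim_config()]) or `inputs`
#' must be supplied. `inputs` is a list with elements `samples` (a list of
#' `list(path, format, sample_id, patient, condition)`) and `meta_path`
#' (cell-metadata TSV with sample-prefixed `cell_id`).
#'
#' @param simulate Optional list of [sim_config()] arguments.
#' @param inputs Optional input description (see above).
#' @param clone_mode Clonotype key definition, see [clone_key()].
#' @param unit Pairing unit, `"cells"` or `"clonotypes"`.
#' @param cluster_threshold CDR3 similarity threshold.
#' @param cluster_chain Chain whose CDR3 is clustered.
#' @param alpha Significance level used in the summary report.
#' @param bootstrap_B,bootstrap_depth Bootstrap replicates and depth policy
#'   for [bootstrap_diversity()].
#' @param subset Optional subset restriction applied to clonotype calling
#'   and pairing.
#' @param seed Integer seed governing simulation and bootstrap.
#' @return Validated list of class `"run_config"`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       clone_mode = "strict", unit = "cells",
                       cluster_threshold = 0.85, cluster_chain = "TRA",
                       alpha = 0.05, bootstrap_B = 100L,
                       bootstrap_depth = "min_sample", subset = NULL,
                       seed = 1L) {
  if (is.null(simulate) == is.null(inputs))
    stop("exactly one of 'simulate' or 'inputs' must be given")
  if (!is.null(inputs)) {
    if (!all(c("samples", "meta_path") %in% names(inputs)))
      stop("inputs needs elements 'samples' and 'meta_path'")
    for (s in inputs$samples)
      if (!all(c("path", "format", "sample_id") %in% names(s)))
        stop("each input sample needs path, format and sample_id")
  }
  stopifnot(clone_mode %in% c("strict", "gene", "nt", "aa"),
            unit %in% c("cells", "clonotypes"),
            cluster_threshold > 0, cluster_threshold <= 1,
            alpha > 0, alpha < 1, bootstrap_B >= 2L)
  structure(list(simulate = simulate, inputs = inputs,
                 clone_mode = clone_mode, unit = unit,
                 cluster_threshold = cluster_threshold,
                 cluster_chain = cluster_chain, alpha = alpha,
                 bootstrap_B = as.integer(bootstrap_B),
                 bootstrap_depth = bootstrap_depth, subset = subset,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.write_tsv <- function(x, dir, name) {
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  name
}

#' Run the full paired-repertoire pipeline
#'
#' Executes reading/simulation, chain filtering, clonotype calling,
#' descriptive clonal statistics, diversity with bootstrap and paired
#' tests, Morisita-Horn overlap, CDR3 positional/k-mer features, gene
#' usage, pairing arrays with CMH and per-pair Fisher tests, and CDR3
#' clustering; writes every table to `outdir` plus a `manifest.json`
#' recording the configuration, filter counts and an md5 per output file.
#' Identical configuration and seed give an identical manifest hash.
#'
#' @param config A `run_config`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list of class `"tcr_pipeline"` holding the stage
#'   tables and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)

  ## -- input stage -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(cohort)
    cells <- cohort_cells(cohort)
  } else {
    cohort <- NULL
    contigs <- do.call(rbind, lapply(config$inputs$samples, function(s) {
      standardize_barcodes(read_contigs(s$path, s$format), s$sample_id)
    }))
    meta <- utils::read.delim(config$inputs$meta_path,
                              stringsAsFactors = FALSE)
    cells <- attach_metadata(filter_chains(contigs), meta)
  }
  flog <- attr(cells, "filter_log")
  flog$dropped_no_metadata <- attr(cells, "dropped_cells")
  files <- c(files, .write_tsv(cells, outdir, "filtered_cells.tsv"))
  jsonlite::write_json(flog, file.path(outdir, "filter_log.json"),
                       auto_unbox = TRUE)
  files <- c(files, "filter_log.json")

  ## -- clonotypes --------------------------------------------------------
  tabs <- call_clonotypes(cells, mode = config$clone_mode,
                          subset = config$subset)
  clono_long <- do.call(rbind, lapply(tabs, function(t)
    data.frame(sample = attr(t, "sample"), clone = t$clone, n = t$n,
               p = t$p, mode = attr(t, "mode"), stringsAsFactors = FALSE)))
  rownames(clono_long) <- NULL
  files <- c(files, .write_tsv(clono_long, outdir, "clonotype_tables.tsv"))

  bins <- do.call(rbind, lapply(names(tabs), function(nm)
    cbind(sample = nm, bin_clone_sizes(tabs[[nm]]))))
  files <- c(files, .write_tsv(bins, outdir, "size_bins.tsv"))

  ucf <- data.frame(
    sample = names(tabs),
    patient = vapply(tabs, function(t) attr(t, "patient"), ""),
    condition = vapply(tabs, function(t) attr(t, "condition"), ""),
    unique_fraction_clonotypes = vapply(tabs, unique_clone_fraction, 0),
    unique_fraction_cells = vapply(tabs, unique_clone_fraction, 0,
                                   denominator = "cells"),
    stringsAsFactors = FALSE)
  rownames(ucf) <- NULL
  files <- c(files, .write_tsv(ucf, outdir, "unique_clone_fraction.tsv"))

  lens <- do.call(rbind, lapply(c("TRA", "TRB", "both"), function(ch)
    cdr3_length_distribution(cells, ch)))
  files <- c(files, .write_tsv(lens, outdir, "cdr3_lengths.tsv"))

  patients <- sort(unique(cells$patient))
  paired <- patients[vapply(patients, function(p)
    all(paste(p, c("pre_GFD", "post_GFD"), sep = "|") %in% names(tabs)),
    TRUE)]
  empty_flow <- data.frame(patient = character(0), clone = character(0),
                           freq_pre = numeric(0), freq_post = numeric(0),
                           status = character(0))
  flows <- do.call(rbind, lapply(paired, function(p)
    cbind(patient = p,
          top_clones_flow(tabs[[paste(p, "pre_GFD", sep = "|")]],
                          tabs[[paste(p, "post_GFD", sep = "|")]]))))
  if (is.null(flows)) flows <- empty_flow
  files <- c(files, .write_tsv(flows, outdir, "top_clone_flows.tsv"))
  scatter <- do.call(rbind, lapply(paired, function(p)
    cbind(patient = p,
          clonal_scatter(tabs[[paste(p, "pre_GFD", sep = "|")]],
                         tabs[[paste(p, "post_GFD", sep = "|")]]))))
  if (is.null(scatter))
    scatter <- data.frame(patient = character(0), clone = character(0),
                          p_pre = numeric(0), p_post = numeric(0))
  files <- c(files, .write_tsv(scatter, outdir, "clonal_scatter.tsv"))

  ## -- diversity / overlap ----------------------------------------------
  div <- bootstrap_diversity(tabs, B = config$bootstrap_B,
                             depth = config$bootstrap_depth,
                             seed = config$seed)
  files <- c(files, .write_tsv(div, outdir, "diversity.tsv"))

  div_tests <- do.call(rbind, lapply(
    c("H", "inv_simpson", "gini_simpson", "norm_entropy", "chao1", "ace"),
    function(ix) {
      pre <- div[[ix]][match(paste(paired, "pre_GFD", sep = "|"),
                             div$sample)]
      post <- div[[ix]][match(paste(paired, "post_GFD", sep = "|"),
                              div$sample)]
      if (length(paired) >= 2L)
        cbind(index = ix, paired_condition_test(pre, post))
      else NULL
    }))
  if (!is.null(div_tests))
    files <- c(files, .write_tsv(div_tests, outdir,
                                 "diversity_paired_tests.tsv"))

  om <- overlap_matrix(tabs)
  files <- c(files, .write_tsv(cbind(sample = rownames(om),
                                     as.data.frame(om)), outdir,
                               "overlap_matrix.tsv"))
  files <- c(files, .write_tsv(overlap_long(om), outdir,
                               "overlap_long.tsv"))

  ## -- sequence features -------------------------------------------------
  feat_rows <- list(); ent_rows <- list(); atch_rows <- list()
  for (cond in sort(unique(cells$condition))) {
    for (ch in c("TRA", "TRB")) {
      col <- if (ch == "TRA") "tra_cdr3_aa" else "trb_cdr3_aa"
      seqs <- cells[[col]][cells$condition == cond]
      prof <- positional_aa_frequency(seqs)
      lab <- paste(cond, ch, sep = "|")
      feat_rows[[lab]] <- data.frame(condition = cond, chain = ch,
                                     position = seq_len(nrow(prof$freq)),
                                     coverage = prof$coverage,
                                     prof$freq, stringsAsFactors = FALSE)
      ent <- positional_entropy(prof)
      ent_rows[[lab]] <- data.frame(condition = cond, chain = ch,
                                    position = as.integer(names(ent)),
                                    entropy = unname(ent),
                                    stringsAsFactors = FALSE)
      at <- positional_atchley(seqs)
      atch_rows[[lab]] <- data.frame(condition = cond, chain = ch,
                                     position = as.integer(rownames(at)),
                                     at, stringsAsFactors = FALSE)
    }
  }
  files <- c(files, .write_tsv(do.call(rbind, feat_rows), outdir,
                               "positional_frequency.tsv"))
  files <- c(files, .write_tsv(do.call(rbind, ent_rows), outdir,
                               "positional_entropy.tsv"))
  files <- c(files, .write_tsv(do.call(rbind, atch_rows), outdir,
                               "positional_atchley.tsv"))

  km_aa <- do.call(rbind, lapply(sort(unique(cells$condition)), function(cd)
    cbind(condition = cd,
          kmer_percentages(c(cells$tra_cdr3_aa, cells$trb_cdr3_aa)[
            rep(cells$condition == cd, 2)], k = 3, alphabet = "aa",
            top = 50))))
  files <- c(files, .write_tsv(km_aa, outdir, "kmers_aa.tsv"))
  km_nt <- do.call(rbind, lapply(sort(unique(cells$condition)), function(cd)
    cbind(condition = cd,
          kmer_percentages(c(cells$tra_cdr3_nt, cells$trb_cdr3_nt)[
            rep(cells$condition == cd, 2)], k = 3, alphabet = "nt",
            top = 50))))
  files <- c(files, .write_tsv(km_nt, outdir, "kmers_nt.tsv"))

  ## -- gene usage and pairing -------------------------------------------
  for (cl in c("TRAV", "TRBV", "TRAJ", "TRBJ")) {
    gu <- gene_usage(cells, cl)
    files <- c(files, .write_tsv(gu$per_sample, outdir,
                                 sprintf("gene_usage_%s_per_sample.tsv", cl)))
    files <- c(files, .write_tsv(gu$per_condition, outdir,
                                 sprintf("gene_usage_%s_per_condition.tsv",
                                         cl)))
  }

  parr <- pairing_array(cells, "TRAV", "TRBV", strata = "condition",
                        unit = config$unit, subset = config$subset)
  files <- c(files, .write_tsv(pairing_long(parr), outdir,
                               "pairing_counts.tsv"))
  both_conds <- all(c("pre_GFD", "post_GFD") %in% unique(cells$condition))
  pair_tests <- if (both_conds) per_pair_fisher(parr) else NULL
  if (!is.null(pair_tests))
    files <- c(files, .write_tsv(pair_tests, outdir, "pair_tests.tsv"))

  cmh <- list()
  if (both_conds) {
    # Default arrangement: pairing category x condition, stratified by
    # patient -- the direct test of "does the pairing distribution differ
    # between conditions".
    pair_cat <- paste(cells$tra_v, cells$trb_v, sep = "|")
    arrB <- table(factor(pair_cat), factor(cells$condition),
                  factor(cells$patient))
    cmh$pairing_by_condition_strat_patient <-
      unclass(cmh_general(unclass(arrB),
                          "pairing x condition | strata = patient"))
    # Comparison arrangement: TRAV x TRBV stratified by condition.
    cmh$trav_by_trbv_strat_condition <-
      unclass(cmh_general(unclass(parr),
                          "TRAV x TRBV | strata = condition"))
    # Single-chain pairings, same default arrangement.
    for (combo in list(c("tra_v", "tra_j", "TRAV_TRAJ"),
                       c("trb_v", "trb_j", "TRBV_TRBJ"))) {
      pc <- paste(cells[[combo[1]]], cells[[combo[2]]], sep = "|")
      a3 <- table(factor(pc), factor(cells$condition),
                  factor(cells$patient))
      cmh[[paste0(combo[3], "_by_condition_strat_patient")]] <-
        unclass(cmh_general(unclass(a3),
                            paste(combo[3],
                                  "x condition | strata = patient")))
    }
  }
  jsonlite::write_json(cmh, file.path(outdir, "cmh.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "cmh.json")

  ## -- clustering --------------------------------------------------------
  cl_col <- if (config$cluster_chain == "TRA") "tra_cdr3_aa"
            else "trb_cdr3_aa"
  node_rows <- list(); edge_rows <- list()
  for (p in patients) {
    sub <- cells[cells$patient == p, , drop = FALSE]
    key <- clone_key(sub, config$clone_mode)
    cl_in <- stats::aggregate(list(size = rep(1L, nrow(sub))),
                              by = list(cdr3 = sub[[cl_col]],
                                        condition = sub$condition,
                                        clone = key),
                              FUN = sum)
    graph <- cluster_clones(cl_in, threshold = config$cluster_threshold,
                            chain = config$cluster_chain)
    node_rows[[p]] <- cbind(patient = p, graph$nodes)
    if (nrow(graph$edges) > 0L)
      edge_rows[[p]] <- cbind(patient = p, graph$edges)
  }
  files <- c(files, .write_tsv(do.call(rbind, node_rows), outdir,
                               "network_nodes.tsv"))
  edge_tbl <- if (length(edge_rows) > 0L) do.call(rbind, edge_rows)
              else data.frame(patient = character(0), from = character(0),
                              to = character(0), similarity = numeric(0))
  files <- c(files, .write_tsv(edge_tbl, outdir, "network_edges.tsv"))

  ## -- summary and manifest ---------------------------------------------
  result <- list(cells = cells, tabs = tabs, unique_fraction = ucf,
                 diversity = div, diversity_tests = div_tests,
                 overlap = om, pair_tests = pair_tests, cmh = cmh,
                 flows = flows, config = config, cohort = cohort,
                 outdir = outdir)
  summary_tbl <- compare_conditions(result)
  files <- c(files, .write_tsv(summary_tbl, outdir, "summary.tsv"))

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  hashes <- unname(tools::md5sum(file.path(outdir, files)))
  names(hashes) <- files
  tf2 <- tempfile()
  writeLines(c(cfg_hash, paste(names(hashes), hashes, sep = ":")), tf2)
  manifest_hash <- unname(tools::md5sum(tf2)); unlink(tf2)
  manifest <- list(package = "pairedTCR",
                   version = as.character(utils::packageVersion("pairedTCR")),
                   seed = config$seed, config_hash = cfg_hash,
                   filter_log = flog, n_cells = nrow(cells),
                   n_samples = length(tabs),
                   files = as.list(hashes),
                   manifest_hash = manifest_hash)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result$manifest <- manifest
  class(result) <- "tcr_pipeline"
  invisible(result)
}

#' Cohort-level pre/post summary
#'
#' Per-patient and cohort-level contrasts assembled from the stage tables
#' of a pipeline run (no recomputation): unique-clone-fraction deltas, the
#' per-index paired t-tests, and the strongest pairing shifts by |log OR|.
#'
#' @param result A `tcr_pipeline` object (or the equivalent list).
#' @return Data.frame with columns `section`, `item`, `patient`, `value`,
#'   `note`.
#' @export
compare_conditions <- function(result) {
  ucf <- result$unique_fraction
  conds <- unique(ucf$condition)
  if (!all(c("pre_GFD", "post_GFD") %in% conds)) {
    return(data.frame(section = "error", item = "conditions",
                      patient = NA_character_, value = NA_real_,
                      note = "both conditions required for comparison",
                      stringsAsFactors = FALSE))
  }
  wide <- merge(ucf[ucf$condition == "pre_GFD",
                    c("patient", "unique_fraction_clonotypes")],
                ucf[ucf$condition == "post_GFD",
                    c("patient", "unique_fraction_clonotypes")],
                by = "patient", suffixes = c("_pre", "_post"))
  if (nrow(wide) < 2L) {
    return(data.frame(section = "error", item = "patients",
                      patient = NA_character_, value = NA_real_,
                      note = "need both conditions for >= 2 patients",
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  rows$ucf <- data.frame(
    section = "unique_clone_fraction", item = "delta_post_minus_pre",
    patient = wide$patient,
    value = wide$unique_fraction_clonotypes_post -
      wide$unique_fraction_clonotypes_pre,
    note = "", stringsAsFactors = FALSE)
  tt <- paired_condition_test(wide$unique_fraction_clonotypes_pre,
                              wide$unique_fraction_clonotypes_post)
  rows$ucf_t <- data.frame(section = "unique_clone_fraction",
                           item = c("paired_t", "paired_p"),
                           patient = NA_character_,
                           value = c(tt$t, tt$p), note = tt$note,
                           stringsAsFactors = FALSE)
  if (!is.null(result$diversity_tests)) {
    dt <- result$diversity_tests
    rows$div <- data.frame(section = "diversity_paired_test",
                           item = paste0(dt$index, "_p"),
                           patient = NA_character_, value = dt$p,
                           note = dt$note, stringsAsFactors = FALSE)
  }
  if (!is.null(result$pair_tests)) {
    pt <- result$pair_tests
    topk <- utils::head(pt[order(-abs(pt$log_or)), , drop = FALSE], 5L)
    rows$pairs <- data.frame(
      section = "top_pairing_shift",
      item = paste(topk$gene_a, topk$gene_b, topk$direction, sep = "|"),
      patient = NA_character_, value = topk$log_or,
      note = sprintf("p_adj=%.3g", topk$p_adj), stringsAsFactors = FALSE)
  }
  if (length(result$cmh) > 0L)
    rows$cmh <- data.frame(
      section = "cmh", item = names(result$cmh), patient = NA_character_,
      value = vapply(result$cmh, function(x) x$p, 0),
      note = vapply(result$cmh, function(x) x$arrangement, ""),
      stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.tcr_pipeline <- function(x, ...) {
  cat("Paired TCR repertoire pipeline run\n")
  cat(sprintf("  %d cells, %d samples -> %s\n", nrow(x$cells),
              length(x$tabs), x$outdir))
  cat(sprintf("  manifest hash: %s\n", x$manifest$manifest_hash))
  invisible(x)
}
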