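# Seeded generator of paired pre/post repertoires with known ground truth.
#
# The generator emulates a 5-patient, two-condition longitudinal design:
# per-patient V/J usage drawn around cohort means, a clone-size model with a
# truncated-geometric body and a uniform expanded tail, post-intervention
# contraction/persistence of clones, and optional condition-specific
# TRAV-TRBV pairing effects on the joint pair distribution. All randomness
# flows from one seed through a fixed draw order; any reordering of draws is
# a breaking change.

.default_trav_pool <- c("TRAV1-2", "TRAV2", "TRAV3", "TRAV4", "TRAV5",
                        "TRAV6", "TRAV8-2", "TRAV9-2", "TRAV10", "TRAV12-1",
                        "TRAV12-2", "TRAV13-1", "TRAV17", "TRAV19", "TRAV21",
                        "TRAV26-1", "TRAV26-2", "TRAV29", "TRAV35",
                        "TRAV38-1")
.default_trbv_pool <- c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-1", "TRBV6-2",
                        "TRBV7-2", "TRBV7-9", "TRBV9", "TRBV11-2",
                        "TRBV12-3", "TRBV14", "TRBV15", "TRBV18", "TRBV19",
                        "TRBV20-1", "TRBV24-1", "TRBV25-1", "TRBV27",
                        "TRBV28", "TRBV30")
.default_traj_pool <- paste0("TRAJ", c(4, 6, 9, 12, 16, 20, 23, 27, 30, 33,
                                       37, 40, 43, 45, 49, 53))
.default_trbj_pool <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4",
                        "TRBJ1-5", "TRBJ1-6", "TRBJ2-1", "TRBJ2-2",
                        "TRBJ2-3", "TRBJ2-4", "TRBJ2-5", "TRBJ2-6",
                        "TRBJ2-7")

# Truncated geometric on 1..5 for the clone-size body; success probability
# fixed so singletons dominate (~60% of clones), matching a repertoire where
# most clonotypes are seen once.
.geom_body_p <- 0.6
.geom_body_max <- 5L

.codon_table <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), M = "ATG",
  N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))
.codon_flat <- unlist(.codon_table, use.names = FALSE)
.codon_len <- lengths(.codon_table)
.codon_off <- c(0L, cumsum(.codon_len))[seq_along(.codon_len)]

#' Default condition-specific pairing effects
#'
#' Six TRAV-TRBV pairs with |log-odds| ln 8 on the joint pair distribution:
#' two applied in the post condition (enriched after intervention) and four
#' applied in the pre condition (depleted after intervention). Marginal V
#' usage is left untouched; only the joint distribution is tilted.
#'
#' @return A data.frame with columns `trav`, `trbv`, `log_odds`, `condition`.
#' @export
default_pairing_effects <- function() {
  data.frame(
    trav = c("TRAV12-2", "TRAV10", "TRAV2", "TRAV26-2", "TRAV2", "TRAV26-1"),
    trbv = c("TRBV14", "TRBV28", "TRBV6-2", "TRBV7-2", "TRBV7-2", "TRBV19"),
    log_odds = rep(log(8), 6L),
    condition = c("post_GFD", "post_GFD", "pre_GFD", "pre_GFD", "pre_GFD",
                  "pre_GFD"),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic paired cohort
#'
#' @param n_patients Number of patients (two samples each: `pre_GFD`,
#'   `post_GFD`).
#' @param cells_per_sample Integer, per-patient integer vector, or `NULL`
#'   (default) to draw each patient's per-sample size uniformly from
#'   1500--3500 cells. The same target applies to both conditions of a
#'   patient.
#' @param trav_pool,trbv_pool,traj_pool,trbj_pool Gene segment name pools.
#' @param usage_concentration Dirichlet concentration for the cohort-level
#'   usage vectors (larger = flatter cohort usage).
#' @param patient_noise Patient-level usage dispersion; patient usage is
#'   Dirichlet with concentration `cohort_mean / patient_noise` (smaller =
#'   patients closer to the cohort mean).
#' @param expanded_fraction_pre Probability a pre-condition clone is drawn
#'   from the expanded tail.
#' @param expanded_size_range Integer interval for expanded clone sizes;
#'   must lie within `[2, 100]` so no hyperexpanded (>100 cell) clone is
#'   emitted by default.
#' @param contraction_factor Multiplier applied to a persisting clone's size
#'   post-intervention, in `(0, 1]`.
#' @param persistence_prob Probability a pre clone persists post.
#' @param pairing_effects `NULL` or a data.frame as returned by
#'   [default_pairing_effects()]; `condition` may be `"pre_GFD"`,
#'   `"post_GFD"` or `"both"`.
#' @param cdr3_length_support Integer interval of CDR3 amino-acid lengths.
#' @param cdr3_length_mode Mode of the triangular length distribution.
#' @param subset_probs Named probabilities over `CD4`, `CD8`, `Treg`,
#'   `other` for non-expanded clones.
#' @param expanded_cd8_prob Probability an expanded clone is labelled CD8
#'   (expansions concentrate in the cytotoxic compartment).
#' @param seed Integer seed; identical configs give byte-identical cohorts.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 5L,
                       cells_per_sample = NULL,
                       trav_pool = .default_trav_pool,
                       trbv_pool = .default_trbv_pool,
                       traj_pool = .default_traj_pool,
                       trbj_pool = .default_trbj_pool,
                       usage_concentration = 5,
                       patient_noise = 0.05,
                       expanded_fraction_pre = 0.02,
                       expanded_size_range = c(6L, 100L),
                       contraction_factor = 0.3,
                       persistence_prob = 0.6,
                       pairing_effects = default_pairing_effects(),
                       cdr3_length_support = c(8L, 20L),
                       cdr3_length_mode = 14L,
                       subset_probs = c(CD4 = 0.58, CD8 = 0.38,
                                        Treg = 0.03, other = 0.01),
                       expanded_cd8_prob = 0.8,
                       seed = 1L) {
  stopifnot(n_patients >= 1L,
            length(trav_pool) > 0L, length(trbv_pool) > 0L,
            length(traj_pool) > 0L, length(trbj_pool) > 0L,
            usage_concentration > 0, patient_noise > 0,
            expanded_fraction_pre >= 0, expanded_fraction_pre <= 1,
            length(expanded_size_range) == 2L,
            expanded_size_range[1] >= 2L, expanded_size_range[2] <= 100L,
            expanded_size_range[1] <= expanded_size_range[2],
            contraction_factor > 0, contraction_factor <= 1,
            persistence_prob >= 0, persistence_prob <= 1,
            length(cdr3_length_support) == 2L,
            cdr3_length_support[1] >= 3L,
            cdr3_length_mode >= cdr3_length_support[1],
            cdr3_length_mode <= cdr3_length_support[2],
            abs(sum(subset_probs) - 1) < 1e-8)
  if (!is.null(pairing_effects)) {
    stopifnot(is.data.frame(pairing_effects),
              all(c("trav", "trbv", "log_odds", "condition") %in%
                    names(pairing_effects)))
    known <- pairing_effects$trav %in% trav_pool &
             pairing_effects$trbv %in% trbv_pool
    if (!all(known))
      stop("pairing_effects reference genes absent from the pools")
    if (!all(pairing_effects$condition %in%
             c("pre_GFD", "post_GFD", "both")))
      stop("pairing_effects$condition must be pre_GFD, post_GFD or both")
  }
  if (!is.null(cells_per_sample)) {
    cells_per_sample <- as.integer(cells_per_sample)
    if (!length(cells_per_sample) %in% c(1L, n_patients))
      stop("cells_per_sample must be scalar or length n_patients")
    if (any(cells_per_sample < 1L)) stop("cells_per_sample must be positive")
  }
  cfg <- list(n_patients = as.integer(n_patients),
              cells_per_sample = cells_per_sample,
              trav_pool = trav_pool, trbv_pool = trbv_pool,
              traj_pool = traj_pool, trbj_pool = trbj_pool,
              usage_concentration = usage_concentration,
              patient_noise = patient_noise,
              expanded_fraction_pre = expanded_fraction_pre,
              expanded_size_range = as.integer(expanded_size_range),
              contraction_factor = contraction_factor,
              persistence_prob = persistence_prob,
              pairing_effects = pairing_effects,
              cdr3_length_support = as.integer(cdr3_length_support),
              cdr3_length_mode = as.integer(cdr3_length_mode),
              subset_probs = subset_probs,
              expanded_cd8_prob = expanded_cd8_prob,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Discrete triangular distribution on lo..hi with the given mode.
.rtri_len <- function(n, lo, hi, mode) {
  support <- lo:hi
  w <- ifelse(support <= mode,
              (support - lo + 1) / (mode - lo + 1),
              (hi - support + 1) / (hi - mode + 1))
  support[sample.int(length(support), n, replace = TRUE, prob = w)]
}

# Clone sizes for one pre-condition sample: geometric body on 1..5 plus a
# uniform expanded tail, truncating the last clone so sizes sum to n_cells.
.draw_clone_sizes <- function(n_cells, expanded_fraction, size_range) {
  body_p <- .geom_body_p
  body_probs <- body_p * (1 - body_p)^(0:(.geom_body_max - 1L))
  body_probs <- body_probs / sum(body_probs)
  mean_size <- expanded_fraction * mean(size_range) +
    (1 - expanded_fraction) * sum((1:.geom_body_max) * body_probs)
  sizes <- integer(0)
  expanded <- logical(0)
  total <- 0L
  while (total < n_cells) {
    blk <- max(32L, ceiling((n_cells - total) / mean_size * 1.2))
    is_exp <- stats::runif(blk) < expanded_fraction
    s <- integer(blk)
    n_exp <- sum(is_exp)
    if (n_exp > 0L)
      s[is_exp] <- sample(size_range[1]:size_range[2], n_exp, replace = TRUE)
    if (n_exp < blk)
      s[!is_exp] <- sample.int(.geom_body_max, blk - n_exp, replace = TRUE,
                               prob = body_probs)
    sizes <- c(sizes, s)
    expanded <- c(expanded, is_exp)
    total <- total + sum(s)
  }
  cs <- cumsum(sizes)
  k <- which(cs >= n_cells)[1]
  sizes <- sizes[seq_len(k)]
  expanded <- expanded[seq_len(k)]
  sizes[k] <- sizes[k] - (cs[k] - n_cells)
  expanded[k] <- expanded[k] && sizes[k] >= size_range[1]
  list(sizes = sizes, expanded = expanded)
}

.make_cdr3 <- function(lens) {
  n <- length(lens)
  if (n == 0L) return(character(0))
  interior <- lens - 2L
  res <- sample(.aa_alphabet, sum(interior), replace = TRUE)
  grp <- factor(rep(seq_len(n), interior), levels = seq_len(n))
  body <- vapply(split(res, grp), paste, "", collapse = "")
  paste0("C", body, "F")
}

.backtranslate <- function(aa_seqs) {
  if (length(aa_seqs) == 0L) return(character(0))
  chars <- strsplit(paste(aa_seqs, collapse = ""), "")[[1]]
  idx <- match(chars, names(.codon_table))
  pick <- floor(stats::runif(length(chars)) * .codon_len[idx]) + 1L
  codons <- .codon_flat[.codon_off[idx] + pick]
  grp <- factor(rep(seq_along(aa_seqs), nchar(aa_seqs)),
                levels = seq_along(aa_seqs))
  vapply(split(codons, grp), paste, "", collapse = "")
}

# Joint TRAV x TRBV pair probabilities for one condition:
# p_ij proportional to p_i * q_j * exp(log_odds) for affected pairs.
.pair_probs <- function(p_trav, p_trbv, effects, condition,
                        trav_pool, trbv_pool) {
  P <- outer(p_trav, p_trbv)
  if (!is.null(effects) && nrow(effects) > 0L) {
    hit <- effects$condition == condition | effects$condition == "both"
    eff <- effects[hit, , drop = FALSE]
    if (nrow(eff) > 0L) {
      i <- match(eff$trav, trav_pool)
      j <- match(eff$trbv, trbv_pool)
      P[cbind(i, j)] <- P[cbind(i, j)] * exp(eff$log_odds)
    }
  }
  P / sum(P)
}

#' Simulate a paired pre/post cohort with ground truth
#'
#' Draw order per run: cohort-level usage vectors (TRAV, TRAJ, TRBV, TRBJ),
#' per-patient sample sizes (when not fixed), then per patient: usage
#' vectors, pre clone sizes, pre clone genes/CDR3s/subsets, persistence and
#' contraction, novel post clones, and finally per-cell UMI counts
#' (pre sample then post sample).
#'
#' @param config A [sim_config()] object.
#' @param dir Optional directory; when given, per-sample AIRR TSVs, the
#'   cell-metadata TSV, the ground-truth JSON and the config YAML are
#'   written there.
#' @return A list of class `"tcr_cohort"` with elements `samples` (named
#'   list of AIRR-dialect contig data.frames, one per patient x condition),
#'   `meta` (cell metadata with sample-prefixed `cell_id`), `truth` (clone
#'   table, pairing effects, per-sample unique-clone fractions) and
#'   `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nA <- length(config$trav_pool); nB <- length(config$trbv_pool)
  cohort_usage <- list(
    trav = .rdirichlet1(rep(config$usage_concentration, nA)),
    traj = .rdirichlet1(rep(config$usage_concentration,
                            length(config$traj_pool))),
    trbv = .rdirichlet1(rep(config$usage_concentration, nB)),
    trbj = .rdirichlet1(rep(config$usage_concentration,
                            length(config$trbj_pool))))
  cps <- config$cells_per_sample
  if (is.null(cps)) {
    cps <- sample(1500:3500, config$n_patients, replace = TRUE)
  } else if (length(cps) == 1L) {
    cps <- rep(cps, config$n_patients)
  }
  if (config$expanded_fraction_pre > 0 &&
      config$expanded_size_range[2] > min(cps))
    stop("infeasible config: expanded clone sizes can exceed cells_per_sample")
  patients <- sprintf("PT%02d", seq_len(config$n_patients))
  samples <- list()
  meta_list <- list()
  clone_rows <- list()
  for (p in seq_len(config$n_patients)) {
    pat <- patients[p]
    usage <- lapply(names(cohort_usage), function(nm)
      .rdirichlet1(cohort_usage[[nm]] / config$patient_noise))
    names(usage) <- names(cohort_usage)
    P_pre <- .pair_probs(usage$trav, usage$trbv, config$pairing_effects,
                         "pre_GFD", config$trav_pool, config$trbv_pool)
    P_post <- .pair_probs(usage$trav, usage$trbv, config$pairing_effects,
                          "post_GFD", config$trav_pool, config$trbv_pool)

    drawn <- .draw_clone_sizes(cps[p], config$expanded_fraction_pre,
                               config$expanded_size_range)
    n_pre <- length(drawn$sizes)
    pre <- .draw_clone_attrs(n_pre, P_pre, usage, config)
    pre$size <- drawn$sizes
    pre$expanded <- drawn$expanded
    pre$subset <- .draw_subsets(drawn$expanded, config)
    pre$clone_id <- sprintf("%s_c%05d", pat, seq_len(n_pre))

    persist <- stats::runif(n_pre) < config$persistence_prob
    post_size <- ifelse(persist,
                        pmax(1L, as.integer(round(drawn$sizes *
                                                  config$contraction_factor))),
                        0L)
    n_novel <- cps[p] - sum(post_size)
    novel <- .draw_clone_attrs(n_novel, P_post, usage, config)
    novel$size <- rep(1L, n_novel)
    novel$expanded <- rep(FALSE, n_novel)
    novel$subset <- .draw_subsets(rep(FALSE, n_novel), config)
    novel$clone_id <- sprintf("%s_n%05d", pat, seq_len(n_novel))

    pre_tbl <- data.frame(patient = pat, condition = "pre_GFD",
                          clone_id = pre$clone_id, size = pre$size,
                          expanded = pre$expanded,
                          fate = ifelse(persist, "persisting", "lost"),
                          trav = pre$trav, traj = pre$traj, trac = pre$trac,
                          trbv = pre$trbv, trbj = pre$trbj, trbc = pre$trbc,
                          tra_cdr3_aa = pre$cdr3a, trb_cdr3_aa = pre$cdr3b,
                          tra_cdr3_nt = pre$nta, trb_cdr3_nt = pre$ntb,
                          subset = pre$subset, stringsAsFactors = FALSE)
    keep <- which(persist)
    post_tbl <- rbind(
      if (length(keep) > 0L)
        transform(pre_tbl[keep, , drop = FALSE], condition = "post_GFD",
                  size = post_size[keep], fate = "persisting")
      else NULL,
      if (n_novel > 0L)
        data.frame(patient = pat, condition = "post_GFD",
                   clone_id = novel$clone_id, size = novel$size,
                   expanded = novel$expanded, fate = "novel",
                   trav = novel$trav, traj = novel$traj, trac = novel$trac,
                   trbv = novel$trbv, trbj = novel$trbj, trbc = novel$trbc,
                   tra_cdr3_aa = novel$cdr3a, trb_cdr3_aa = novel$cdr3b,
                   tra_cdr3_nt = novel$nta, trb_cdr3_nt = novel$ntb,
                   subset = novel$subset, stringsAsFactors = FALSE)
      else NULL)
    rownames(post_tbl) <- NULL
    for (cond_tbl in list(pre_tbl, post_tbl)) {
      cond <- cond_tbl$condition[1]
      sample_id <- paste(pat, cond, sep = "_")
      emitted <- .emit_sample(cond_tbl, sample_id)
      samples[[sample_id]] <- emitted$contigs
      meta_list[[sample_id]] <- emitted$meta
    }
    clone_rows[[pat]] <- rbind(pre_tbl, post_tbl)
  }
  clones <- do.call(rbind, clone_rows)
  rownames(clones) <- NULL
  uf <- stats::aggregate(list(n_clones = clones$size),
                         by = list(patient = clones$patient,
                                   condition = clones$condition),
                         FUN = length)
  uf1 <- stats::aggregate(list(n_singletons = clones$size == 1L),
                          by = list(patient = clones$patient,
                                    condition = clones$condition),
                          FUN = sum)
  uf$n_singletons <- uf1$n_singletons[match(paste(uf$patient, uf$condition),
                                            paste(uf1$patient,
                                                  uf1$condition))]
  uf$unique_clone_fraction <- uf$n_singletons / uf$n_clones
  truth <- list(clones = clones,
                pair_effects = if (is.null(config$pairing_effects))
                  default_pairing_effects()[0, ] else config$pairing_effects,
                unique_clone_fraction = uf,
                cells_per_sample = stats::setNames(cps, patients))
  out <- list(samples = samples,
              meta = do.call(rbind, c(meta_list, list(make.row.names = FALSE))),
              truth = truth, config = config)
  class(out) <- "tcr_cohort"
  if (!is.null(dir)) .write_cohort(out, dir)
  out
}

.draw_clone_attrs <- function(n, P, usage, config) {
  if (n < 0L) stop("internal error: negative clone count requested")
  nA <- length(config$trav_pool)
  pair_idx <- if (n > 0L)
    sample.int(length(P), n, replace = TRUE, prob = as.vector(P))
  else integer(0)
  i <- ((pair_idx - 1L) %% nA) + 1L
  j <- ((pair_idx - 1L) %/% nA) + 1L
  traj <- sample(config$traj_pool, max(n, 1L), replace = TRUE,
                 prob = usage$traj)[seq_len(n)]
  trbj <- sample(config$trbj_pool, max(n, 1L), replace = TRUE,
                 prob = usage$trbj)[seq_len(n)]
  trbc <- sample(c("TRBC1", "TRBC2"), max(n, 1L),
                 replace = TRUE)[seq_len(n)]
  la <- .rtri_len(n, config$cdr3_length_support[1],
                  config$cdr3_length_support[2], config$cdr3_length_mode)
  lb <- .rtri_len(n, config$cdr3_length_support[1],
                  config$cdr3_length_support[2], config$cdr3_length_mode)
  cdr3a <- .make_cdr3(la)
  cdr3b <- .make_cdr3(lb)
  list(trav = config$trav_pool[i], trbv = config$trbv_pool[j],
       traj = traj, trbj = trbj, trac = rep("TRAC", n), trbc = trbc,
       cdr3a = cdr3a, cdr3b = cdr3b,
       nta = .backtranslate(cdr3a), ntb = .backtranslate(cdr3b))
}

.draw_subsets <- function(expanded, config) {
  n <- length(expanded)
  if (n == 0L) return(character(0))
  subs <- sample(names(config$subset_probs), n, replace = TRUE,
                 prob = config$subset_probs)
  n_exp <- sum(expanded)
  if (n_exp > 0L) {
    cd8 <- stats::runif(n_exp) < config$expanded_cd8_prob
    subs[expanded][cd8] <- "CD8"
  }
  subs
}

# One contig table (AIRR dialect, unprefixed barcodes) plus metadata rows
# (sample-prefixed ids) for a single sample's clone table.
.emit_sample <- function(clone_tbl, sample_id) {
  n_cells <- sum(clone_tbl$size)
  idx <- rep(seq_len(nrow(clone_tbl)), clone_tbl$size)
  bc <- sprintf("bc%06d-1", seq_len(n_cells))
  umis_a <- 1L + stats::rpois(n_cells, 3)
  umis_b <- 1L + stats::rpois(n_cells, 3)
  tra <- data.frame(cell_id = bc, locus = "TRA",
                    v_call = clone_tbl$trav[idx],
                    j_call = clone_tbl$traj[idx],
                    c_call = clone_tbl$trac[idx],
                    junction = clone_tbl$tra_cdr3_nt[idx],
                    junction_aa = clone_tbl$tra_cdr3_aa[idx],
                    duplicate_count = umis_a, productive = "TRUE",
                    stringsAsFactors = FALSE)
  trb <- data.frame(cell_id = bc, locus = "TRB",
                    v_call = clone_tbl$trbv[idx],
                    j_call = clone_tbl$trbj[idx],
                    c_call = clone_tbl$trbc[idx],
                    junction = clone_tbl$trb_cdr3_nt[idx],
                    junction_aa = clone_tbl$trb_cdr3_aa[idx],
                    duplicate_count = umis_b, productive = "TRUE",
                    stringsAsFactors = FALSE)
  contigs <- rbind(tra, trb)
  contigs <- contigs[order(match(contigs$cell_id, bc), contigs$locus), ,
                     drop = FALSE]
  rownames(contigs) <- NULL
  meta <- data.frame(cell_id = paste0(sample_id, "_", bc),
                     patient = clone_tbl$patient[idx],
                     condition = clone_tbl$condition[idx],
                     subset = clone_tbl$subset[idx],
                     stringsAsFactors = FALSE)
  list(contigs = contigs, meta = meta)
}

.write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(cohort$samples))
    utils::write.table(cohort$samples[[nm]],
                       file.path(dir, paste0(nm, "_contigs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$meta, file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "sim_truth.json"),
                       dataframe = "columns", digits = NA)
  cfg <- cohort$config
  cfg$pairing_effects <- if (is.null(cfg$pairing_effects)) NULL else
    as.list(cfg$pairing_effects)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Paired cells of a synthetic cohort
#'
#' Convenience wrapper running the standard input stage on a simulated
#' cohort: barcode standardization per sample, chain filtering and
#' metadata attachment.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Cell data.frame with metadata attached (see
#'   [attach_metadata()]).
#' @export
cohort_cells <- function(cohort) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  contigs <- do.call(rbind, lapply(names(cohort$samples), function(nm) {
    df <- cohort$samples[[nm]]
    standardize_barcodes(
      data.frame(barcode = df$cell_id, locus = df$locus,
                 v_call = df$v_call, j_call = df$j_call,
                 c_call = df$c_call, cdr3_nt = df$junction,
                 cdr3_aa = df$junction_aa,
                 umis = as.integer(df$duplicate_count),
                 productive = TRUE, stringsAsFactors = FALSE), nm)
  }))
  attach_metadata(filter_chains(contigs), cohort$meta)
}

#' Tabular summary of the simulation ground truth
#'
#' One row per injected pairing effect (its true log-odds and the condition
#' it tilts) and one row per patient-level unique-clone-fraction contrast
#' (post minus pre), suitable for joining against pipeline estimates.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @return A data.frame with columns `kind`, `patient`, `gene_a`, `gene_b`,
#'   `condition`, `true_value`.
#' @export
ground_truth_report <- function(truth) {
  eff <- truth$pair_effects
  rows_eff <- if (nrow(eff) > 0L)
    data.frame(kind = "pairing_log_odds", patient = NA_character_,
               gene_a = eff$trav, gene_b = eff$trbv,
               condition = eff$condition, true_value = eff$log_odds,
               stringsAsFactors = FALSE)
  else
    data.frame(kind = character(0), patient = character(0),
               gene_a = character(0), gene_b = character(0),
               condition = character(0), true_value = numeric(0),
               stringsAsFactors = FALSE)
  uf <- truth$unique_clone_fraction
  wide <- merge(uf[uf$condition == "pre_GFD",
                   c("patient", "unique_clone_fraction")],
                uf[uf$condition == "post_GFD",
                   c("patient", "unique_clone_fraction")],
                by = "patient", suffixes = c("_pre", "_post"))
  rows_uf <- data.frame(kind = "unique_clone_fraction_delta",
                        patient = wide$patient,
                        gene_a = NA_character_, gene_b = NA_character_,
                        condition = "post_minus_pre",
                        true_value = wide$unique_clone_fraction_post -
                          wide$unique_clone_fraction_pre,
                        stringsAsFactors = FALSE)
  rbind(rows_eff, rows_uf)
}

#' @export
print.tcr_cohort <- function(x, ...) {
  n_cells <- sum(vapply(x$samples, function(s) length(unique(s$cell_id)), 0L))
  cat("Synthetic paired TCR cohort\n")
  cat(sprintf("  %d patients, %d samples, %d cells (seed %d)\n",
              x$config$n_patients, length(x$samples), n_cells,
              x$config$seed))
  cat(sprintf("  pairing effects: %d; contraction %.2f, persistence %.2f\n",
              nrow(x$truth$pair_effects), x$config$contraction_factor,
              x$config$persistence_prob))
  invisible(x)
}
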