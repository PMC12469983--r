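# Clonotype calling and descriptive clonal statistics.
#
# A clonotype key is built from both chains (TRA component first). Four
# definitions are exposed: "gene" (V/J/C segments of both chains), "nt"
# (both nucleotide CDR3s), "aa" (both amino-acid CDR3s), and "strict"
# (genes + nucleotide CDR3s, the default).

.size_bin_breaks <- c(0, 1, 5, 20, 100, Inf)
.size_bin_labels <- c("Single", "Small", "Medium", "Large", "Hyperexpanded")

#' Build clonotype keys for paired cells
#'
#' @param cells Cell data.frame (see [filter_chains()]).
#' @param mode One of `"strict"`, `"gene"`, `"nt"`, `"aa"`.
#' @return Character vector of keys, one per cell.
#' @export
clone_key <- function(cells, mode = c("strict", "gene", "nt", "aa")) {
  mode <- match.arg(mode)
  gene <- paste0(cells$tra_v, "_", cells$tra_j, "_", cells$tra_c, "|",
                 cells$trb_v, "_", cells$trb_j, "_", cells$trb_c)
  nt <- paste0(cells$tra_cdr3_nt, "|", cells$trb_cdr3_nt)
  switch(mode,
         gene = gene,
         nt = nt,
         aa = paste0(cells$tra_cdr3_aa, "|", cells$trb_cdr3_aa),
         strict = paste0(gene, ";", nt))
}

#' Construct a clonotype table from clone counts
#'
#' Low-level constructor used when counts are already known (tests,
#' simulations). [call_clonotypes()] is the cell-level entry point.
#'
#' @param n Positive integer clone sizes.
#' @param clone Optional clone keys (defaults to `clone_1`, ...).
#' @param sample,patient,condition Sample annotations stored as attributes.
#' @param mode Clone-key mode annotation.
#' @return A `clonotype_tbl` data.frame with columns `clone`, `n`, `p`.
#' @export
clonotype_table <- function(n, clone = NULL, sample = "sample_1",
                            patient = NA_character_,
                            condition = NA_character_, mode = "strict") {
  n <- as.integer(n)
  stopifnot(all(n >= 1L))
  if (is.null(clone)) clone <- sprintf("clone_%d", seq_along(n))
  stopifnot(!anyDuplicated(clone))
  tab <- data.frame(clone = as.character(clone), n = n, p = n / sum(n),
                    stringsAsFactors = FALSE)
  o <- order(-tab$n, tab$clone, method = "radix")
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "sample") <- sample
  attr(tab, "patient") <- patient
  attr(tab, "condition") <- condition
  attr(tab, "mode") <- mode
  attr(tab, "N") <- sum(n)
  class(tab) <- c("clonotype_tbl", "data.frame")
  tab
}

#' Call clonotypes per sample
#'
#' Aggregates cells sharing a clone key within each `(patient, condition)`
#' sample. An optional `subset` restriction (e.g. `"CD8"`) is applied before
#' counting; proportions are renormalized within the restricted sample.
#'
#' @param cells Cell data.frame with metadata attached
#'   ([attach_metadata()] output, or any data.frame with the chain columns
#'   plus `patient` and `condition`).
#' @param mode Clone-key mode, see [clone_key()].
#' @param subset Optional subset label(s) to restrict to.
#' @return Named list of `clonotype_tbl` objects, keyed `patient|condition`.
#' @export
call_clonotypes <- function(cells, mode = c("strict", "gene", "nt", "aa"),
                            subset = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("patient", "condition") %in% names(cells)))
  if (!is.null(subset)) {
    if (!"subset" %in% names(cells))
      stop("cells carry no subset column")
    cells <- cells[cells$subset %in% subset, , drop = FALSE]
  }
  key <- clone_key(cells, mode)
  samp <- paste(cells$patient, cells$condition, sep = "|")
  out <- lapply(split(seq_len(nrow(cells)), samp), function(idx) {
    counts <- table(key[idx])
    clonotype_table(as.integer(counts), clone = names(counts),
                    sample = samp[idx[1]],
                    patient = cells$patient[idx[1]],
                    condition = cells$condition[idx[1]],
                    mode = mode)
  })
  if (length(out) == 0L) warning("no cells to call clonotypes on")
  out
}

#' Clone-size bins and occupied repertoire space
#'
#' Bins partition the positive integers as Single `[1]`, Small `[2,5]`,
#' Medium `[6,20]`, Large `[21,100]`, Hyperexpanded `(100, Inf)`. For each
#' bin the clone count and the fraction of cells it occupies (the occupied
#' repertoire space) are reported.
#'
#' @param table A `clonotype_tbl`.
#' @param breaks Optional alternative bin edges (passed to [cut()] as
#'   right-closed breaks starting at 0).
#' @return Data.frame with columns `bin`, `clones`, `cells`, `cell_prop`.
#' @export
bin_clone_sizes <- function(table, breaks = .size_bin_breaks) {
  stopifnot(nrow(table) > 0L)
  labels <- if (identical(breaks, .size_bin_breaks)) .size_bin_labels
            else paste0("(", head(breaks, -1), ",", breaks[-1], "]")
  bin <- cut(table$n, breaks = breaks, labels = labels, right = TRUE)
  clones <- as.integer(table(bin))
  cells <- as.integer(tapply(table$n, bin, sum, default = 0L))
  data.frame(bin = labels, clones = clones, cells = cells,
             cell_prop = cells / sum(table$n), stringsAsFactors = FALSE)
}

#' Fraction of clonotypes seen exactly once
#'
#' By default the denominator is the number of clonotypes; the cell
#' denominator (singleton cells over all cells) is available because the
#' quantity is reported both ways in the literature.
#'
#' @param table A `clonotype_tbl`.
#' @param denominator `"clonotypes"` or `"cells"`.
#' @return A single numeric value.
#' @export
unique_clone_fraction <- function(table,
                                  denominator = c("clonotypes", "cells")) {
  denominator <- match.arg(denominator)
  stopifnot(nrow(table) > 0L)
  f1 <- sum(table$n == 1L)
  if (denominator == "clonotypes") f1 / nrow(table)
  else f1 / sum(table$n)
}

#' CDR3 amino-acid length distribution
#'
#' Counts CDR3 lengths per sample (or pooled when no sample annotation is
#' present). `chain = "both"` pools the two per-chain distributions, so the
#' histogram mass equals the number of chains considered, not cells.
#'
#' @param cells Cell data.frame.
#' @param chain `"TRA"`, `"TRB"` or `"both"`.
#' @return Data.frame with columns `sample`, `chain`, `length`, `count`.
#' @export
cdr3_length_distribution <- function(cells, chain = c("both", "TRA", "TRB")) {
  chain <- match.arg(chain)
  samp <- if ("patient" %in% names(cells) && "condition" %in% names(cells))
    paste(cells$patient, cells$condition, sep = "|")
  else rep("all", nrow(cells))
  lens <- switch(chain,
                 TRA = list(len = nchar(cells$tra_cdr3_aa), samp = samp),
                 TRB = list(len = nchar(cells$trb_cdr3_aa), samp = samp),
                 both = list(len = c(nchar(cells$tra_cdr3_aa),
                                     nchar(cells$trb_cdr3_aa)),
                             samp = c(samp, samp)))
  if (length(lens$len) == 0L)
    return(data.frame(sample = character(0), chain = character(0),
                      length = integer(0), count = integer(0)))
  tab <- as.data.frame(table(sample = lens$samp, length = lens$len),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  out <- data.frame(sample = tab$sample, chain = chain,
                    length = as.integer(tab$length),
                    count = as.integer(tab$Freq), stringsAsFactors = FALSE)
  out[order(out$sample, out$length), , drop = FALSE]
}

#' Flow of top clones between paired samples
#'
#' Takes the union of the top-`n` clonotypes of each table and reports each
#' clone's frequency in both samples plus its fate: `persisting` (present in
#' both), `lost` (pre only) or `novel` (post only).
#'
#' @param pre,post `clonotype_tbl` objects from the same patient.
#' @param n Number of top clones per table.
#' @return Data.frame with columns `clone`, `freq_pre`, `freq_post`,
#'   `status`.
#' @export
top_clones_flow <- function(pre, post, n = 10L) {
  if (!identical(attr(pre, "patient"), attr(post, "patient")))
    stop("pre and post tables come from different patients")
  top_of <- function(tab) tab$clone[seq_len(min(n, nrow(tab)))]
  keys <- union(top_of(pre), top_of(post))
  fp <- pre$p[match(keys, pre$clone)]
  fq <- post$p[match(keys, post$clone)]
  in_pre <- !is.na(fp); in_post <- !is.na(fq)
  fp[!in_pre] <- 0; fq[!in_post] <- 0
  status <- ifelse(in_pre & in_post, "persisting",
                   ifelse(in_pre, "lost", "novel"))
  out <- data.frame(clone = keys, freq_pre = fp, freq_post = fq,
                    status = status, stringsAsFactors = FALSE)
  out[order(-pmax(out$freq_pre, out$freq_post), out$clone), , drop = FALSE]
}

#' Per-clone proportions across a sample pair
#'
#' One row per clonotype in the union of the two tables, with zero
#' proportions where absent; the raw material of a pre/post scatter plot.
#'
#' @param pre,post `clonotype_tbl` objects from the same patient.
#' @return Data.frame with columns `clone`, `p_pre`, `p_post`.
#' @export
clonal_scatter <- function(pre, post) {
  if (!identical(attr(pre, "patient"), attr(post, "patient")))
    stop("pre and post tables come from different patients")
  keys <- union(pre$clone, post$clone)
  p1 <- pre$p[match(keys, pre$clone)]
  p2 <- post$p[match(keys, post$clone)]
  p1[is.na(p1)] <- 0; p2[is.na(p2)] <- 0
  data.frame(clone = keys, p_pre = p1, p_post = p2,
             stringsAsFactors = FALSE)
}
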