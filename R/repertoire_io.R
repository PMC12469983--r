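# Contig table IO and chain-level filtering.
#
# Two dialects are supported: the 10x Genomics filtered_contig_annotations.csv
# contract and the AIRR Rearrangement TSV contract. Both are reduced to a
# common contig data.frame with one row per chain observation.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.tenx_required <- c("barcode", "chain", "v_gene", "j_gene", "c_gene", "cdr3",
                    "cdr3_nt", "umis", "productive", "is_cell",
                    "high_confidence")
.airr_required <- c("cell_id", "locus", "v_call", "j_call", "c_call",
                    "junction", "junction_aa", "duplicate_count", "productive")

# Allele suffixes ("TRAV10*01" -> "TRAV10") are stripped because downstream
# analyses are at gene, not allele, resolution.
strip_allele <- function(x) sub("\\*.*$", "", as.character(x))

.as_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  toupper(trimws(as.character(x))) %in% c("TRUE", "T", "YES", "Y", "1")
}

#' Read a V(D)J contig table
#'
#' Parses a per-sample contig annotation file into a contig data.frame with
#' one row per productive TRA/TRB chain observation. Non-productive contigs,
#' loci other than TRA/TRB, and (for the 10x dialect) rows not flagged as
#' both `is_cell` and `high_confidence` are dropped. V/J/C allele suffixes
#' (`*01`) are stripped. Rows whose CDR3 amino-acid sequence contains
#' characters outside the 20-letter alphabet, or whose V call prefix
#' contradicts the locus, are rejected and counted.
#'
#' @param path Path to the contig file.
#' @param format `"tenx_csv"` for 10x `filtered_contig_annotations.csv`,
#'   `"airr_tsv"` for an AIRR Rearrangement TSV.
#' @return A data.frame with columns `barcode`, `locus`, `v_call`, `j_call`,
#'   `c_call`, `cdr3_nt`, `cdr3_aa`, `umis`, `productive`. The number of
#'   rejected rows is attached as attribute `"rejected_rows"`.
#' @examples
#' airr <- system.file("extdata", "example_contigs_airr.tsv",
#'                     package = "pairedTCR")
#' head(read_contigs(airr, format = "airr_tsv"))
#' @export
read_contigs <- function(path, format = c("tenx_csv", "airr_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("contig file not found: ", path)
  if (format == "tenx_csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(.tenx_required, names(raw))
    if (length(miss) > 0L)
      stop("missing mandatory column(s) in 10x contig table: ",
           paste(miss, collapse = ", "))
    raw <- raw[.as_flag(raw$is_cell) & .as_flag(raw$high_confidence), ,
               drop = FALSE]
    out <- data.frame(barcode    = as.character(raw$barcode),
                      locus      = as.character(raw$chain),
                      v_call     = strip_allele(raw$v_gene),
                      j_call     = strip_allele(raw$j_gene),
                      c_call     = strip_allele(raw$c_gene),
                      cdr3_nt    = as.character(raw$cdr3_nt),
                      cdr3_aa    = as.character(raw$cdr3),
                      umis       = suppressWarnings(as.integer(raw$umis)),
                      productive = .as_flag(raw$productive),
                      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    miss <- setdiff(.airr_required, names(raw))
    if (length(miss) > 0L)
      stop("missing mandatory column(s) in AIRR rearrangement table: ",
           paste(miss, collapse = ", "))
    out <- data.frame(barcode    = as.character(raw$cell_id),
                      locus      = as.character(raw$locus),
                      v_call     = strip_allele(raw$v_call),
                      j_call     = strip_allele(raw$j_call),
                      c_call     = strip_allele(raw$c_call),
                      cdr3_nt    = as.character(raw$junction),
                      cdr3_aa    = as.character(raw$junction_aa),
                      umis       = suppressWarnings(as.integer(raw$duplicate_count)),
                      productive = .as_flag(raw$productive),
                      stringsAsFactors = FALSE)
  }
  out <- out[out$productive & out$locus %in% c("TRA", "TRB"), , drop = FALSE]
  bad_aa <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", out$cdr3_aa)
  bad_locus <- (out$locus == "TRA" & !startsWith(out$v_call, "TRAV")) |
               (out$locus == "TRB" & !startsWith(out$v_call, "TRBV"))
  bad <- bad_aa | bad_locus
  n_rej <- sum(bad)
  if (n_rej > 0L)
    message(n_rej, " contig row(s) rejected (CDR3 alphabet or locus/V-call mismatch)")
  out <- out[!bad, , drop = FALSE]
  out$umis[is.na(out$umis)] <- 0L
  rownames(out) <- NULL
  attr(out, "rejected_rows") <- n_rej
  out
}

#' Prefix barcodes with a sample identifier
#'
#' Cell barcodes are made globally unique by prefixing `sample_id` and an
#' underscore. The operation is idempotent: barcodes already carrying the
#' prefix are left unchanged.
#'
#' @param records Contig data.frame from [read_contigs()].
#' @param sample_id Non-empty sample identifier string.
#' @return `records` with standardized `barcode` values.
#' @export
standardize_barcodes <- function(records, sample_id) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("sample_id must be a single non-empty string")
  prefix <- paste0(sample_id, "_")
  bc <- records$barcode
  records$barcode <- ifelse(startsWith(bc, prefix), bc, paste0(prefix, bc))
  records
}

#' Resolve each barcode to a single alpha/beta chain pair
#'
#' Per barcode and locus the single highest-UMI productive chain is kept;
#' ties on UMI count are broken by the lexicographically smallest nucleotide
#' CDR3 so the result is independent of input order. Barcodes lacking either
#' a TRA or a TRB chain after resolution are removed. The removal counts are
#' attached as the `"filter_log"` attribute.
#'
#' @param records Barcode-standardized contig data.frame.
#' @return A cell data.frame, one row per surviving barcode, with columns
#'   `cell_id` and, for each chain prefix `tra_`/`trb_`: `v`, `j`, `c`,
#'   `cdr3_nt`, `cdr3_aa`, `umis`.
#' @export
filter_chains <- function(records) {
  stopifnot(is.data.frame(records))
  rec <- records[records$productive & records$locus %in% c("TRA", "TRB"), ,
                 drop = FALSE]
  n_bc_in <- length(unique(records$barcode))
  if (nrow(rec) == 0L) {
    cells <- .empty_cells()
    attr(cells, "filter_log") <- list(input_barcodes = n_bc_in, cells = 0L,
                                      no_tra = 0L, no_trb = 0L,
                                      extra_chains_dropped = 0L)
    return(cells)
  }
  o <- order(rec$barcode, rec$locus, -rec$umis, rec$cdr3_nt, method = "radix")
  rec <- rec[o, , drop = FALSE]
  key <- paste(rec$barcode, rec$locus, sep = "\r")
  first <- !duplicated(key)
  extra <- sum(!first)
  best <- rec[first, , drop = FALSE]
  tra <- best[best$locus == "TRA", , drop = FALSE]
  trb <- best[best$locus == "TRB", , drop = FALSE]
  common <- sort(intersect(tra$barcode, trb$barcode))
  no_trb <- length(setdiff(tra$barcode, common))
  no_tra <- length(setdiff(trb$barcode, common))
  ia <- match(common, tra$barcode)
  ib <- match(common, trb$barcode)
  cells <- data.frame(cell_id     = common,
                      tra_v       = tra$v_call[ia],
                      tra_j       = tra$j_call[ia],
                      tra_c       = tra$c_call[ia],
                      tra_cdr3_nt = tra$cdr3_nt[ia],
                      tra_cdr3_aa = tra$cdr3_aa[ia],
                      tra_umis    = tra$umis[ia],
                      trb_v       = trb$v_call[ib],
                      trb_j       = trb$j_call[ib],
                      trb_c       = trb$c_call[ib],
                      trb_cdr3_nt = trb$cdr3_nt[ib],
                      trb_cdr3_aa = trb$cdr3_aa[ib],
                      trb_umis    = trb$umis[ib],
                      stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  attr(cells, "filter_log") <- list(input_barcodes = n_bc_in,
                                    cells = nrow(cells),
                                    no_tra = no_tra, no_trb = no_trb,
                                    extra_chains_dropped = extra)
  cells
}

.empty_cells <- function() {
  data.frame(cell_id = character(0),
             tra_v = character(0), tra_j = character(0), tra_c = character(0),
             tra_cdr3_nt = character(0), tra_cdr3_aa = character(0),
             tra_umis = integer(0),
             trb_v = character(0), trb_j = character(0), trb_c = character(0),
             trb_cdr3_nt = character(0), trb_cdr3_aa = character(0),
             trb_umis = integer(0),
             stringsAsFactors = FALSE)
}

#' Join cell metadata onto paired-chain cells
#'
#' Inner join on `cell_id`; cells without metadata are dropped and counted
#' (attribute `"dropped_cells"`). The `(patient, condition)` pair defines a
#' sample and is concatenated into a `sample` column.
#'
#' @param cells Cell data.frame from [filter_chains()].
#' @param meta Data.frame with columns `cell_id`, `patient`, `condition`,
#'   `subset` (and optionally `subcluster`). `cell_id` must be unique.
#' @return `cells` with metadata columns appended.
#' @export
attach_metadata <- function(cells, meta) {
  req <- c("cell_id", "patient", "condition", "subset")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0L)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$cell_id))
    stop("duplicate cell_id in metadata")
  m <- match(cells$cell_id, meta$cell_id)
  dropped <- sum(is.na(m))
  keep <- !is.na(m)
  if (!any(keep) && nrow(cells) > 0L)
    warning("no cells matched the metadata; result is empty")
  out <- cells[keep, , drop = FALSE]
  mm <- m[keep]
  out$patient <- as.character(meta$patient[mm])
  out$condition <- as.character(meta$condition[mm])
  out$subset <- as.character(meta$subset[mm])
  if ("subcluster" %in% names(meta))
    out$subcluster <- as.character(meta$subcluster[mm])
  out$sample <- paste(out$patient, out$condition, sep = "|")
  rownames(out) <- NULL
  attr(out, "dropped_cells") <- dropped
  attr(out, "filter_log") <- attr(cells, "filter_log")
  out
}

#' Write paired cells back out as an AIRR Rearrangement TSV
#'
#' Emits two rows per cell (TRA then TRB) using the AIRR column contract
#' understood by [read_contigs()], so a write/read/filter round trip
#' reproduces the cell records exactly.
#'
#' @param cells Cell data.frame from [filter_chains()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(cells, path) {
  row_for <- function(prefix, locus) {
    data.frame(cell_id = cells$cell_id,
               locus = locus,
               v_call = cells[[paste0(prefix, "_v")]],
               j_call = cells[[paste0(prefix, "_j")]],
               c_call = cells[[paste0(prefix, "_c")]],
               junction = cells[[paste0(prefix, "_cdr3_nt")]],
               junction_aa = cells[[paste0(prefix, "_cdr3_aa")]],
               duplicate_count = cells[[paste0(prefix, "_umis")]],
               productive = "TRUE",
               stringsAsFactors = FALSE)
  }
  out <- rbind(row_for("tra", "TRA"), row_for("trb", "TRB"))
  out <- out[order(out$cell_id, out$locus), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
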