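# CDR3 positional composition, entropy, Atchley-factor profiles, k-mers.
#
# Sequences are left-aligned; the denominator at position p is the total
# weight of sequences of length >= p, so each covered position is a proper
# distribution over the 20 amino acids. Weights default to clone cell
# counts when supplied (repertoire-level composition); weight 1 per
# sequence gives the unique-clonotype reading.

#' Atchley factors for the 20 amino acids
#'
#' The five numerical factor scores summarizing amino-acid physicochemical
#' properties (Atchley et al. 2005, PNAS 102:6395-6400): F1 polarity/
#' hydrophobicity, F2 secondary structure, F3 size/bulkiness, F4 codon
#' composition, F5 charge.
#'
#' @format A 20 x 5 numeric matrix, rows named by one-letter amino-acid
#'   code, columns `F1`..`F5`.
#' @export
atchley_factors <- matrix(c(
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512   # Y
), nrow = 20, ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  paste0("F", 1:5)))

.check_weights <- function(seqs, weights) {
  if (is.null(weights)) weights <- rep(1, length(seqs))
  if (length(weights) == 1L) weights <- rep(weights, length(seqs))
  stopifnot(length(weights) == length(seqs), all(weights >= 0))
  weights
}

.drop_invalid_aa <- function(seqs, weights) {
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", seqs)
  if (!all(ok))
    message(sum(!ok), " sequence(s) rejected: invalid amino-acid residue")
  list(seqs = seqs[ok], weights = weights[ok], rejected = sum(!ok))
}

#' Positional amino-acid frequency profile
#'
#' @param cdr3s Character vector of CDR3 amino-acid sequences.
#' @param weights Per-sequence weights (clone cell counts), recycled scalar
#'   allowed; default 1.
#' @return List of class `"positional_profile"`: `freq` (L_max x 20 matrix,
#'   rows summing to 1 where covered), `coverage` (per-position total
#'   weight), `rejected` (count of invalid sequences).
#' @export
positional_aa_frequency <- function(cdr3s, weights = NULL) {
  weights <- .check_weights(cdr3s, weights)
  v <- .drop_invalid_aa(cdr3s, weights)
  seqs <- v$seqs; w <- v$weights
  L <- nchar(seqs)
  L_max <- if (length(L) > 0L) max(L) else 0L
  freq <- matrix(0, nrow = L_max, ncol = 20,
                 dimnames = list(NULL, .aa_alphabet))
  coverage <- numeric(L_max)
  for (pos in seq_len(L_max)) {
    i <- L >= pos
    ch <- substr(seqs[i], pos, pos)
    acc <- rowsum(w[i], ch)
    coverage[pos] <- sum(acc)
    freq[pos, rownames(acc)] <- acc[, 1] / coverage[pos]
  }
  structure(list(freq = freq, coverage = coverage, rejected = v$rejected),
            class = "positional_profile")
}

#' Normalized positional entropy
#'
#' `-sum_a f log f / log 20` per covered position, so invariant positions
#' score 0 and a uniform position scores 1. Positions with zero coverage
#' are omitted.
#'
#' @param profile A `positional_profile`.
#' @return Named numeric vector (names = positions).
#' @export
positional_entropy <- function(profile) {
  stopifnot(inherits(profile, "positional_profile"))
  keep <- which(profile$coverage > 0)
  ent <- vapply(keep, function(pos) {
    f <- profile$freq[pos, ]
    f <- f[f > 0]
    -sum(f * log(f)) / log(20)
  }, 0)
  stats::setNames(ent, keep)
}

#' Positional Atchley-factor means
#'
#' Weighted mean of each of the five Atchley factors at each covered
#' position, using the same coverage convention as
#' [positional_aa_frequency()].
#'
#' @param cdr3s Character vector of CDR3 amino-acid sequences.
#' @param weights Per-sequence weights; default 1.
#' @return Matrix (covered positions x 5), rownames = positions.
#' @export
positional_atchley <- function(cdr3s, weights = NULL) {
  profile <- positional_aa_frequency(cdr3s, weights)
  keep <- which(profile$coverage > 0)
  out <- profile$freq[keep, , drop = FALSE] %*%
    atchley_factors[colnames(profile$freq), ]
  rownames(out) <- keep
  out
}

#' Weighted k-mer percentage table
#'
#' Sliding window of width `k`, step 1; sequences shorter than `k`
#' contribute nothing; window counts are weighted by clone size and
#' percentages normalized within the input.
#'
#' @param seqs Character vector (nucleotide or amino acid).
#' @param k Window width (>= 1); default 3 (tri-mers).
#' @param weights Per-sequence weights; default 1.
#' @param alphabet `"aa"` or `"nt"`; sequences failing the declared
#'   alphabet are rejected with a message.
#' @param top Optional: keep only the `top` most frequent k-mers.
#' @return Data.frame with columns `kmer`, `count`, `percent`, sorted by
#'   descending count.
#' @export
kmer_percentages <- function(seqs, k = 3L, weights = NULL,
                             alphabet = c("aa", "nt"), top = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(k >= 1L)
  weights <- .check_weights(seqs, weights)
  pat <- if (alphabet == "aa") "^[ACDEFGHIKLMNPQRSTVWY]*$" else "^[ACGTN]*$"
  ok <- grepl(pat, seqs)
  if (!all(ok))
    message(sum(!ok), " sequence(s) rejected: invalid ", alphabet,
            " residue")
  seqs <- seqs[ok]; weights <- weights[ok]
  L <- nchar(seqs)
  n_win <- pmax(L - k + 1L, 0L)
  if (sum(n_win) == 0L)
    return(data.frame(kmer = character(0), count = numeric(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  idx <- rep(seq_along(seqs), n_win)
  start <- unlist(lapply(n_win, seq_len), use.names = FALSE)
  km <- substring(seqs[idx], start, start + k - 1L)
  acc <- rowsum(weights[idx], km)
  out <- data.frame(kmer = rownames(acc), count = acc[, 1],
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$count / sum(out$count)
  out <- out[order(-out$count, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  out
}
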