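# Diversity, evenness and repertoire overlap.
#
# Six indices are computed by direct summation over clone proportions:
# Shannon entropy (nats), inverse Simpson, Gini-Simpson, normalized entropy
# (H / ln S), bias-corrected Chao1, and ACE with the standard rare-abundance
# cutoff of 10. Overlap uses the Morisita-Horn index on proportions, which
# is bounded in [0, 1] (the classic Morisita index on counts is not).

#' Point-estimate diversity profile of a clonotype table
#'
#' @param table A `clonotype_tbl` (or any data.frame with an `n` column of
#'   positive clone sizes).
#' @param rare_cutoff Rare-clone abundance cutoff for ACE (default 10).
#' @param chao1_bias_corrected Use the bias-corrected Chao1
#'   `S + f1(f1-1)/(2(f2+1))` (default); the classic form `S + f1^2/(2 f2)`
#'   is used otherwise, falling back to the bias-corrected form when
#'   `f2 = 0`.
#' @return One-row data.frame with columns `sample`, `N`, `S_obs`, `H`,
#'   `inv_simpson`, `gini_simpson`, `norm_entropy`, `chao1`, `ace`, `f1`,
#'   `f2`, `C_ACE`, `gamma_sq`.
#' @export
diversity_profile <- function(table, rare_cutoff = 10L,
                              chao1_bias_corrected = TRUE) {
  n <- as.numeric(table$n)
  N <- sum(n)
  if (N < 1) stop("empty clonotype table")
  S <- length(n)
  p <- n / N
  H <- -sum(p * log(p))
  sumsq <- sum(p^2)
  f1 <- sum(n == 1)
  f2 <- sum(n == 2)
  chao1 <- if (chao1_bias_corrected || f2 == 0)
    S + f1 * (f1 - 1) / (2 * (f2 + 1))
  else S + f1^2 / (2 * f2)
  rare <- n[n <= rare_cutoff]
  S_rare <- length(rare)
  S_abund <- S - S_rare
  N_rare <- sum(rare)
  if (S_rare == 0L) {
    C_ace <- 1; g2 <- 0; ace <- S
  } else {
    C_ace <- 1 - f1 / N_rare
    if (C_ace == 0 || N_rare <= 1) {
      g2 <- NA_real_
      ace <- chao1   # coverage undefined: fall back to Chao1
    } else {
      fk <- tabulate(rare, nbins = rare_cutoff)
      k <- seq_len(rare_cutoff)
      g2 <- max(S_rare * sum(k * (k - 1) * fk) /
                  (C_ace * N_rare * (N_rare - 1)) - 1, 0)
      ace <- S_abund + S_rare / C_ace + f1 / C_ace * g2
    }
  }
  data.frame(sample = attr(table, "sample") %||% NA_character_,
             N = N, S_obs = S, H = H,
             inv_simpson = 1 / sumsq,
             gini_simpson = 1 - sumsq,
             norm_entropy = if (S > 1) H / log(S) else 0,
             chao1 = chao1, ace = ace,
             f1 = f1, f2 = f2, C_ACE = C_ace, gamma_sq = g2,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.diversity_index_names <- c("S_obs", "H", "inv_simpson", "gini_simpson",
                            "norm_entropy", "chao1", "ace")

#' Bootstrap diversity with downsampling
#'
#' Per replicate, `depth` cells are drawn with replacement from the sample's
#' cell-level multiset and all indices recomputed; the mean and standard
#' deviation over `B` replicates accompany the point estimates. Downsampling
#' to a common depth makes samples of unequal size comparable.
#'
#' @param tables List of `clonotype_tbl` objects.
#' @param B Number of bootstrap replicates (>= 2).
#' @param depth `"min_sample"` (default: smallest N across `tables`) or a
#'   fixed integer not exceeding the smallest N.
#' @param seed Optional integer seed.
#' @return Data.frame, one row per sample: point estimates plus
#'   `boot_mean_*`/`boot_sd_*` per index, `B`, `depth`.
#' @export
bootstrap_diversity <- function(tables, B = 100L, depth = "min_sample",
                                seed = NULL) {
  if (B < 2L) stop("B must be at least 2")
  stopifnot(length(tables) >= 1L)
  Ns <- vapply(tables, function(t) sum(t$n), 0)
  if (any(Ns < 1)) stop("all tables must be non-empty")
  d <- if (identical(depth, "min_sample")) as.integer(min(Ns))
       else as.integer(depth)
  if (d < 1L || d > min(Ns))
    stop("depth must be a positive integer not exceeding the smallest sample")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(tables, function(tab) {
    point <- diversity_profile(tab)
    cells <- rep.int(seq_len(nrow(tab)), tab$n)
    reps <- matrix(NA_real_, nrow = B,
                   ncol = length(.diversity_index_names))
    for (b in seq_len(B)) {
      cnt <- tabulate(cells[sample.int(length(cells), d, replace = TRUE)],
                      nbins = nrow(tab))
      cnt <- cnt[cnt > 0L]
      dv <- diversity_profile(data.frame(n = cnt))
      reps[b, ] <- unlist(dv[.diversity_index_names])
    }
    bm <- colMeans(reps)
    bs <- apply(reps, 2, stats::sd)
    stats <- c(stats::setNames(bm, paste0("boot_mean_",
                                          .diversity_index_names)),
               stats::setNames(bs, paste0("boot_sd_",
                                          .diversity_index_names)))
    cbind(point, as.data.frame(as.list(stats)), B = B, depth = d)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired pre/post t-test on per-patient values
#'
#' Classical paired t-test (df = n - 1) on post - pre differences. When the
#' differences have zero variance the p-value is undefined and flagged
#' rather than fabricated.
#'
#' @param values_pre,values_post Numeric vectors paired by patient, length
#'   >= 2.
#' @return One-row data.frame: `mean_diff`, `t`, `df`, `p`, `note`
#'   (`"ok"` or `"zero_variance"`).
#' @export
paired_condition_test <- function(values_pre, values_post) {
  stopifnot(length(values_pre) == length(values_post),
            length(values_pre) >= 2L)
  d <- values_post - values_pre
  if (stats::sd(d) == 0) {
    return(data.frame(mean_diff = mean(d), t = NA_real_,
                      df = length(d) - 1L, p = NA_real_,
                      note = "zero_variance", stringsAsFactors = FALSE))
  }
  ht <- stats::t.test(values_post, values_pre, paired = TRUE)
  data.frame(mean_diff = mean(d), t = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value, note = "ok",
             stringsAsFactors = FALSE)
}

#' Morisita-Horn overlap between two repertoires
#'
#' `C = 2 sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) X Y)` over the
#' union of clone keys, clamped to `[0, 1]` against rounding. Both tables
#' must have been built under the same clone-key mode.
#'
#' @param a,b `clonotype_tbl` objects.
#' @return Numeric scalar in `[0, 1]`.
#' @export
morisita_overlap <- function(a, b) {
  ma <- attr(a, "mode"); mb <- attr(b, "mode")
  if (!is.null(ma) && !is.null(mb) && !identical(ma, mb))
    stop("clone-key modes differ: ", ma, " vs ", mb)
  stopifnot(nrow(a) > 0L, nrow(b) > 0L)
  keys <- union(a$clone, b$clone)
  x <- numeric(length(keys)); y <- numeric(length(keys))
  x[match(a$clone, keys)] <- a$n
  y[match(b$clone, keys)] <- b$n
  X <- sum(x); Y <- sum(y)
  C <- 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  min(max(C, 0), 1)
}

#' Pairwise Morisita-Horn overlap matrix
#'
#' @param tables Named list of >= 2 `clonotype_tbl` objects.
#' @return Symmetric matrix with unit diagonal; sample names as dimnames.
#' @export
overlap_matrix <- function(tables) {
  stopifnot(length(tables) >= 2L)
  nm <- names(tables) %||%
    vapply(tables, function(t) attr(t, "sample"), "")
  k <- length(tables)
  M <- diag(1, k)
  dimnames(M) <- list(nm, nm)
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k) {
      v <- morisita_overlap(tables[[i]], tables[[j]])
      M[i, j] <- v
      M[j, i] <- v
    }
  M
}

#' Long-form view of an overlap matrix
#'
#' @param m Matrix from [overlap_matrix()].
#' @return Data.frame with columns `sample_a`, `sample_b`, `morisita`, one
#'   row per unordered pair.
#' @export
overlap_long <- function(m) {
  idx <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(sample_a = rownames(m)[idx[, 1]],
             sample_b = colnames(m)[idx[, 2]],
             morisita = m[idx], stringsAsFactors = FALSE)
}
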