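# V/J gene usage, TRAV-TRBV pairing arrays, stratified CMH tests, and
# per-pair Fisher exact tests with odds ratios.
#
# The marginal-stability-versus-pairing-shift contrast is the analytical
# core: per-gene usage is compared per condition, while pairing arrays feed
# a global stratified Cochran-Mantel-Haenszel test and per-pair 2x2 exact
# tests (pair / not-pair x pre / post) with Haldane-Anscombe-corrected odds
# ratios and multiplicity adjustment.

.segment_column <- c(TRAV = "tra_v", TRAJ = "tra_j",
                     TRBV = "trb_v", TRBJ = "trb_j")

#' Gene segment usage frequencies
#'
#' Per-sample counts and proportions for one segment class, plus
#' condition-level aggregates obtained by pooling counts across the
#' condition's samples. Output is dense over the union of observed genes
#' and any configured pool, so vectors are conformable across samples.
#'
#' @param cells Cell data.frame with metadata attached.
#' @param class `"TRAV"`, `"TRAJ"`, `"TRBV"` or `"TRBJ"`.
#' @param pool Optional gene names to force into the output.
#' @return List with data.frames `per_sample` (`sample`, `gene`, `count`,
#'   `prop`) and `per_condition` (`condition`, `gene`, `count`, `prop`).
#' @export
gene_usage <- function(cells, class = c("TRBV", "TRAV", "TRAJ", "TRBJ"),
                       pool = NULL) {
  class <- match.arg(class)
  stopifnot(nrow(cells) > 0L)
  col <- .segment_column[[class]]
  genes <- sort(union(unique(cells[[col]]), pool))
  g <- factor(cells[[col]], levels = genes)
  per_group <- function(grp) {
    tab <- table(grp, g)
    cnt <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(cnt) <- c("group", "gene", "count")
    tot <- rowSums(tab)
    cnt$prop <- cnt$count / tot[cnt$group]
    cnt[order(cnt$group, cnt$gene), , drop = FALSE]
  }
  ps <- per_group(paste(cells$patient, cells$condition, sep = "|"))
  names(ps)[1] <- "sample"
  pc <- per_group(cells$condition)
  names(pc)[1] <- "condition"
  rownames(ps) <- rownames(pc) <- NULL
  list(per_sample = ps, per_condition = pc)
}

#' Gene-pairing contingency array
#'
#' `counts[i, j, k]` = number of units in stratum `k` whose chains use row
#' gene `i` and column gene `j`. Units are cells (default) or clonotypes
#' (each within-sample strict-key clonotype counted once). Axes are dense
#' over the union of observed genes plus optional pools.
#'
#' @param cells Cell data.frame with metadata attached.
#' @param row_class,col_class Segment classes (see [gene_usage()]).
#' @param strata `"condition"` or `"patient"`.
#' @param unit `"cells"` or `"clonotypes"`.
#' @param subset Optional subset restriction (e.g. `"CD4"`).
#' @param row_pool,col_pool Optional gene names to force into the axes.
#' @return 3D integer array with dimnames, class `"pairing_array"`; the
#'   unit is stored in attribute `"unit"`.
#' @export
pairing_array <- function(cells, row_class = "TRAV", col_class = "TRBV",
                          strata = c("condition", "patient"),
                          unit = c("cells", "clonotypes"), subset = NULL,
                          row_pool = NULL, col_pool = NULL) {
  strata <- match.arg(strata)
  unit <- match.arg(unit)
  stopifnot(row_class %in% names(.segment_column),
            col_class %in% names(.segment_column))
  if (!is.null(subset)) cells <- cells[cells$subset %in% subset, ,
                                       drop = FALSE]
  stopifnot(nrow(cells) > 0L)
  if (unit == "clonotypes") {
    key <- paste(cells$patient, cells$condition, clone_key(cells, "strict"),
                 sep = "\r")
    cells <- cells[!duplicated(key), , drop = FALSE]
  }
  rg <- factor(cells[[.segment_column[[row_class]]]],
               levels = sort(union(unique(cells[[.segment_column[[row_class]]]]),
                                   row_pool)))
  cg <- factor(cells[[.segment_column[[col_class]]]],
               levels = sort(union(unique(cells[[.segment_column[[col_class]]]]),
                                   col_pool)))
  st <- factor(cells[[strata]])
  arr <- table(rg, cg, st)
  dimnames(arr) <- list(levels(rg), levels(cg), levels(st))
  arr <- unclass(arr)
  attr(arr, "unit") <- unit
  attr(arr, "row_class") <- row_class
  attr(arr, "col_class") <- col_class
  attr(arr, "strata") <- strata
  class(arr) <- c("pairing_array", class(arr))
  arr
}

#' Long-form view of a pairing array
#'
#' @param arr A `pairing_array`.
#' @return Data.frame with columns `gene_a`, `gene_b`, `stratum`, `count`.
#' @export
pairing_long <- function(arr) {
  d <- dim(arr)
  dn <- dimnames(arr)
  data.frame(gene_a = rep(dn[[1]], times = d[2] * d[3]),
             gene_b = rep(rep(dn[[2]], each = d[1]), times = d[3]),
             stratum = rep(dn[[3]], each = d[1] * d[2]),
             count = as.vector(arr), stringsAsFactors = FALSE)
}

#' Cochran-Mantel-Haenszel test for 2x2xK tables
#'
#' The classical statistic
#' `(|sum_k (a_k - n_1.k m_.1k / n_k)| - 0.5 * correction)^2 /
#'  sum_k n_1.k n_0.k m_.1k m_.0k / (n_k^2 (n_k - 1))`
#' referred to chi-square with 1 df. Strata with a zero margin (or fewer
#' than 2 observations) are skipped and reported.
#'
#' @param tables 2x2xK array (a 2x2 matrix is treated as K = 1).
#' @param correction Apply the 0.5 continuity correction.
#' @return List of class `"cmh_result"`: `statistic`, `df`, `p`,
#'   `arrangement`, `strata_used`, `strata_skipped`.
#' @export
cmh_2x2xk <- function(tables, correction = FALSE) {
  if (length(dim(tables)) == 2L) tables <- array(tables, c(2, 2, 1))
  stopifnot(length(dim(tables)) == 3L, all(dim(tables)[1:2] == 2L))
  K <- dim(tables)[3]
  num <- 0; den <- 0; used <- 0L; skipped <- 0L
  for (k in seq_len(K)) {
    t2 <- tables[, , k]
    n <- sum(t2)
    r <- rowSums(t2); cc <- colSums(t2)
    if (n < 2 || any(r == 0) || any(cc == 0)) { skipped <- skipped + 1L; next }
    num <- num + t2[1, 1] - r[1] * cc[1] / n
    den <- den + r[1] * r[2] * cc[1] * cc[2] / (n^2 * (n - 1))
    used <- used + 1L
  }
  if (used == 0L) stop("all strata degenerate")
  stat <- (abs(num) - 0.5 * correction)^2 / den
  structure(list(statistic = unname(stat), df = 1L,
                 p = stats::pchisq(stat, 1, lower.tail = FALSE),
                 arrangement = "2x2xK",
                 strata_used = used, strata_skipped = skipped),
            class = "cmh_result")
}

#' Generalized Cochran-Mantel-Haenszel test of general association
#'
#' For an I x J x K array: per stratum, the `(I-1)(J-1)` vector of observed
#' minus expected counts under independence given the margins, with its
#' multiple-hypergeometric covariance; the quadratic form of the summed
#' vector in the summed covariance is referred to chi-square with
#' `(I-1)(J-1)` df. When the covariance is singular its eigendecomposition
#' pseudo-inverse is used and df reduces to the rank. Strata with fewer
#' than 2 observations are skipped.
#'
#' @param array I x J x K count array (I, J >= 2).
#' @param arrangement Free-text descriptor of the axis roles, stored in the
#'   result.
#' @return A `"cmh_result"` list: `statistic`, `df`, `p`, `arrangement`,
#'   `strata_used`, `strata_skipped`, `rank_deficient`.
#' @export
cmh_general <- function(array, arrangement = "IxJxK") {
  stopifnot(length(dim(array)) == 3L, all(dim(array)[1:2] >= 2L))
  I <- dim(array)[1]; J <- dim(array)[2]; K <- dim(array)[3]
  m <- (I - 1L) * (J - 1L)
  G <- numeric(m)
  V <- matrix(0, m, m)
  used <- 0L; skipped <- 0L
  for (k in seq_len(K)) {
    Nk <- array[, , k]
    n <- sum(Nk)
    if (n < 2) { skipped <- skipped + 1L; next }
    pr <- rowSums(Nk) / n
    pc <- colSums(Nk) / n
    E <- outer(pr, pc) * n
    G <- G + as.vector((Nk - E)[-I, -J, drop = FALSE])
    Ar <- (diag(pr, nrow = I) - pr %o% pr)[-I, -I, drop = FALSE]
    Bc <- (diag(pc, nrow = J) - pc %o% pc)[-J, -J, drop = FALSE]
    V <- V + (n^2 / (n - 1)) * kronecker(Bc, Ar)
    used <- used + 1L
  }
  if (used == 0L) stop("all strata degenerate")
  e <- eigen(V, symmetric = TRUE)
  tol <- max(e$values, 0) * length(e$values) * .Machine$double.eps * 100
  pos <- e$values > tol
  rank <- sum(pos)
  if (rank == 0L) stop("covariance matrix is zero; no association testable")
  z <- crossprod(e$vectors[, pos, drop = FALSE], G)
  stat <- sum(z^2 / e$values[pos])
  structure(list(statistic = unname(stat), df = rank,
                 p = stats::pchisq(stat, rank, lower.tail = FALSE),
                 arrangement = arrangement,
                 strata_used = used, strata_skipped = skipped,
                 rank_deficient = rank < m),
            class = "cmh_result")
}

#' @export
print.cmh_result <- function(x, ...) {
  cat(sprintf("CMH test (%s): statistic = %.4f, df = %d, p = %.4g\n",
              x$arrangement, x$statistic, x$df, x$p))
  if (x$strata_skipped > 0L)
    cat(sprintf("  (%d degenerate stratum/strata skipped)\n",
                x$strata_skipped))
  invisible(x)
}

# Two-sided Fisher exact p by hypergeometric enumeration: the sum of all
# table probabilities not exceeding the observed one, with a relative
# tolerance of 1e-7 on the comparison (the convention used by exact-test
# implementations to absorb floating-point ties).
.fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0L || k == 0L || k == m + n) return(1)
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d0 <- stats::dhyper(a, m, n, k)
  min(sum(dens[dens <= d0 * (1 + 1e-7)]), 1)
}

#' Per-pair Fisher exact tests across two conditions
#'
#' For every gene pair `(i, j)` a 2x2 presence table is formed: `a` = units
#' with the pair pre, `b` = other pre units, `c` = units with the pair
#' post, `d` = other post units. The two-sided exact p comes from full
#' hypergeometric enumeration; the odds ratio is `ad/bc` (pre odds over
#' post odds), with 0.5 added to all four cells when any is zero
#' (Haldane-Anscombe). `OR < 1` means the pair is more frequent post
#' (`enriched_post`); `OR > 1` means `depleted_post`. Benjamini-Hochberg
#' adjusted p-values are appended.
#'
#' @param array A `pairing_array` whose strata are exactly the two
#'   conditions `pre_GFD` and `post_GFD`.
#' @param adjust_method Multiplicity adjustment, `"BH"` or `"bonferroni"`.
#' @return Data.frame: `gene_a`, `gene_b`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `log_or`, `p`, `p_adj`, `direction`.
#' @export
per_pair_fisher <- function(array, adjust_method = c("BH", "bonferroni")) {
  adjust_method <- match.arg(adjust_method)
  dn <- dimnames(array)
  if (length(dn[[3]]) != 2L ||
      !all(c("pre_GFD", "post_GFD") %in% dn[[3]]))
    stop("array must have exactly the strata pre_GFD and post_GFD")
  pre <- array[, , "pre_GFD"]
  post <- array[, , "post_GFD"]
  T_pre <- sum(pre); T_post <- sum(post)
  if (T_pre == 0L || T_post == 0L) stop("a condition stratum is empty")
  a <- as.vector(pre); cc <- as.vector(post)
  b <- T_pre - a; d <- T_post - cc
  p <- mapply(.fisher_p, a, b, cc, d)
  zero <- a == 0L | b == 0L | cc == 0L | d == 0L
  or <- ifelse(zero,
               (a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5)),
               a * d / (b * cc))
  or[a == 0L & cc == 0L] <- 1   # pair unobserved in both conditions

  direction <- ifelse(or > 1, "depleted_post",
                      ifelse(or < 1, "enriched_post", "none"))
  out <- data.frame(gene_a = rep(dn[[1]], times = length(dn[[2]])),
                    gene_b = rep(dn[[2]], each = length(dn[[1]])),
                    a = a, b = b, c = cc, d = d,
                    odds_ratio = or, log_or = log(or), p = p,
                    p_adj = adjust_pvalues(p, adjust_method),
                    direction = direction, stringsAsFactors = FALSE)
  out[order(out$p, -abs(out$log_or)), , drop = FALSE]
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (default) or Bonferroni, preserving input
#' order.
#'
#' @param ps Numeric p-values in (0, 1].
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(ps, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stats::p.adjust(ps, method = method)
}
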