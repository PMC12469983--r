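# CDR3 similarity clustering.
#
# Nodes are unique CDR3 amino-acid sequences of the chosen chain within a
# group (typically one patient, both conditions pooled, so condition
# sharing is well-defined); edges connect sequences whose normalized
# Levenshtein similarity reaches the threshold; clusters are connected
# components. A length-difference prefilter skips pairs that cannot reach
# the threshold; it is exactly equivalent to the unfiltered computation
# because the edit distance is bounded below by the length difference.

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions, computed by the dynamic-programming algorithm
#' (via [utils::adist()]). Vectorized elementwise with recycling.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @export
cdr3_levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- utils::adist(a[i], b[i])[1, 1]
  out
}

#' Normalized CDR3 similarity
#'
#' `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`, bounded in `[0, 1]`.
#' Two empty strings are defined as identical (similarity 1).
#'
#' @param a,b Character vectors (recycled).
#' @return Numeric vector of similarities.
#' @export
cdr3_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  denom <- pmax(nchar(a), nchar(b))
  d <- cdr3_levenshtein(a, b)
  ifelse(denom == 0L, 1, 1 - d / denom)
}

#' Cluster clonotypes by CDR3 similarity
#'
#' @param clones Data.frame with columns `cdr3` (amino-acid sequence of the
#'   chosen chain), `size` (cell count) and `condition`; one row per
#'   clonotype of one group (e.g. one patient, both conditions).
#' @param threshold Similarity threshold in (0, 1]; default 0.85.
#' @param chain Annotation only (`"TRA"` default, per-chain clustering is
#'   decided by what `cdr3` holds).
#' @return List of class `"clone_graph"`: `nodes` (`id`, `cdr3`, `size`,
#'   `status` in pre_only/post_only/shared, `cluster`), `edges` (`from`,
#'   `to`, `similarity`), `threshold`, `chain`.
#' @export
cluster_clones <- function(clones, threshold = 0.85,
                           chain = c("TRA", "TRB")) {
  chain <- match.arg(chain)
  stopifnot(threshold > 0, threshold <= 1,
            all(c("cdr3", "size", "condition") %in% names(clones)))
  u <- sort(unique(clones$cdr3))
  n <- length(u)
  if (n == 0L) {
    out <- list(nodes = data.frame(id = character(0), cdr3 = character(0),
                                   size = numeric(0), status = character(0),
                                   cluster = integer(0)),
                edges = data.frame(from = character(0), to = character(0),
                                   similarity = numeric(0)),
                threshold = threshold, chain = chain)
    class(out) <- "clone_graph"
    return(out)
  }
  size <- as.vector(rowsum(as.numeric(clones$size),
                           factor(clones$cdr3, levels = u)))
  conds <- split(clones$condition, factor(clones$cdr3, levels = u))
  status <- vapply(conds, function(cs) {
    has_pre <- any(grepl("^pre", cs)); has_post <- any(grepl("^post", cs))
    if (has_pre && has_post) "shared"
    else if (has_pre) "pre_only" else "post_only"
  }, "")
  edges <- .similarity_edges(u, threshold)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(edges$from_idx, edges$to_idx))
  comp <- igraph::components(g)$membership
  nodes <- data.frame(id = u, cdr3 = u, size = size,
                      status = unname(status), cluster = comp,
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  out <- list(nodes = nodes,
              edges = data.frame(from = u[edges$from_idx],
                                 to = u[edges$to_idx],
                                 similarity = edges$similarity,
                                 stringsAsFactors = FALSE),
              threshold = threshold, chain = chain)
  class(out) <- "clone_graph"
  out
}

# All pairs (i < j) with similarity >= threshold, visiting only length
# blocks whose difference can still reach the threshold.
.similarity_edges <- function(u, threshold) {
  empty <- data.frame(from_idx = integer(0), to_idx = integer(0),
                      similarity = numeric(0))
  if (length(u) < 2L) return(empty)
  L <- nchar(u)
  by_len <- split(seq_along(u), L)
  lens <- as.integer(names(by_len))
  rows <- list()
  for (ai in seq_along(lens)) {
    for (bi in ai:length(lens)) {
      la <- lens[ai]; lb <- lens[bi]
      if (lb - la > (1 - threshold) * lb) next
      ia <- by_len[[ai]]; ib <- by_len[[bi]]
      D <- utils::adist(u[ia], u[ib])
      sim <- 1 - D / lb
      hit <- which(sim >= threshold, arr.ind = TRUE)
      if (ai == bi) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit) == 0L) next
      from <- ia[hit[, 1]]; to <- ib[hit[, 2]]
      swap <- from > to
      tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
      rows[[length(rows) + 1L]] <-
        data.frame(from_idx = from, to_idx = to,
                   similarity = sim[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$from_idx, out$to_idx), , drop = FALSE]
}

#' Export a clone graph as plain-text tables
#'
#' @param graph A `clone_graph`.
#' @param edge_path,node_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
export_network <- function(graph, edge_path, node_path) {
  utils::write.table(graph$edges[, c("from", "to", "similarity")],
                     edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, node_path))
}

#' Rebuild a clone graph from exported tables
#'
#' @param edge_path,node_path Paths written by [export_network()].
#' @param threshold,chain Annotations to restore.
#' @return A `clone_graph` isomorphic to the exported one.
#' @export
import_network <- function(edge_path, node_path, threshold = 0.85,
                           chain = "TRA") {
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE,
                             colClasses = c(id = "character",
                                            cdr3 = "character"))
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE,
                             colClasses = c(from = "character",
                                            to = "character"))
  out <- list(nodes = nodes, edges = edges, threshold = threshold,
              chain = chain)
  class(out) <- "clone_graph"
  out
}

#' @export
print.clone_graph <- function(x, ...) {
  cat(sprintf(paste0("CDR3 similarity network (%s, threshold %.2f): ",
                     "%d nodes, %d edges, %d clusters\n"),
              x$chain, x$threshold, nrow(x$nodes), nrow(x$edges),
              if (nrow(x$nodes) > 0L) max(x$nodes$cluster) else 0L))
  invisible(x)
}
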