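# CDR3 amino-acid edit distances and Levenshtein-distance-1 similarity
# networks over abundant clonotypes. CDR3 sequences that differ by a single
# amino acid are commonly assumed to recognize the same antigen, so
# distance-1 neighbors define both the "similar" category of new-clone
# classification and the edges of the similarity network.

#' Levenshtein edit distance between amino-acid strings
#'
#' Standard edit distance (substitutions, insertions and deletions each cost
#' 1), vectorized over pairs with the usual recycling rules. Symmetric and
#' metric; the distance to an empty string is the other string's length.
#'
#' @param a,b character vectors of CDR3 amino-acid sequences.
#' @return an integer vector of pairwise distances.
#' @examples
#' levenshtein("CASSL", "CASTL")   # 1 substitution
#' levenshtein("CASSL", "CASSLF")  # 1 insertion
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- utils::adist(a[i], b[i])[1, 1]
  }
  out
}

# All single-character deletions of each string, as a two-column data frame
# (variant, index of the originating string). Includes the string itself so
# that the symmetric-deletion candidate rule below covers substitutions,
# insertions, deletions and equality in one join.
deletion_variants <- function(x) {
  lens <- nchar(x)
  n_var <- lens + 1L
  idx <- rep(seq_along(x), n_var)
  pos <- sequence(n_var) - 1L  # 0 = the unmodified string
  str <- x[idx]
  variant <- ifelse(pos == 0L, str,
                    paste0(substr(str, 1L, pos - 1L), substr(str, pos + 1L, nchar(str))))
  list(variant = variant, idx = idx)
}

# Fast distance <= 1 candidate search: two strings are within edit distance 1
# only if their deletion neighborhoods (string plus all single deletions)
# intersect. The rule over-generates (e.g. "AB" vs "BA"), so candidates are
# verified with the exact distance.
d1_candidates <- function(queries, pool) {
  qv <- deletion_variants(queries)
  pv <- deletion_variants(pool)
  hit <- pv$variant %in% qv$variant
  if (!any(hit)) return(NULL)
  # pair up every (query, pool) combination sharing a variant; only hitting
  # rows are kept before the joins so the work scales with matches, not pool
  p_var <- pv$variant[hit]
  p_idx <- pv$idx[hit]
  q_keep <- qv$variant %in% p_var
  q_var <- qv$variant[q_keep]
  q_idx <- qv$idx[q_keep]
  shared <- unique(p_var)
  qs <- split(q_idx, factor(q_var, levels = shared))
  ps <- split(p_idx, factor(p_var, levels = shared))
  pairs <- unique(do.call(rbind, lapply(seq_along(shared), function(i) {
    expand.grid(q = unique(qs[[i]]), p = unique(ps[[i]]), KEEP.OUT.ATTRS = FALSE)
  })))
  pairs
}

#' Find edit-distance neighbors of a query in a pool
#'
#' Returns the pool members within Levenshtein distance `d` of the query.
#' For `d = 1` a symmetric-deletion index is used (candidate generation by
#' shared single-deletion variants, then exact verification), which is
#' equivalent to brute-force dynamic programming over the whole pool but
#' scales to large repertoires; larger `d` falls back to a length-pruned
#' exact scan.
#'
#' @param query a single CDR3 amino-acid string.
#' @param pool character vector of CDR3 amino-acid strings.
#' @param d maximum distance (default 1).
#' @param strict drop exact matches (distance 0) from the result
#'   (default `TRUE`).
#' @return the subset of `pool` (unique values) within distance `d`.
#' @export
neighbors <- function(query, pool, d = 1, strict = TRUE) {
  stopifnot(length(query) == 1L, length(pool) >= 1, d >= 0)
  pool_u <- unique(as.character(pool))
  if (d == 1) {
    pairs <- d1_candidates(query, pool_u)
    if (is.null(pairs) || nrow(pairs) == 0) return(character(0))
    cand <- pool_u[unique(pairs$p)]
    keep <- levenshtein(query, cand) <= 1L
    res <- cand[keep]
  } else {
    cand <- pool_u[abs(nchar(pool_u) - nchar(query)) <= d]
    if (length(cand) == 0) return(character(0))
    res <- cand[drop(utils::adist(query, cand)) <= d]
  }
  if (strict) res <- setdiff(res, query)
  res
}

# For each query, is any pool member within distance 1 (exact matches
# excluded)? Vectorized over queries via one shared symmetric-deletion join.
has_d1_neighbor <- function(queries, pool) {
  out <- logical(length(queries))
  if (length(pool) == 0 || length(queries) == 0) return(out)
  pairs <- d1_candidates(unique(queries), unique(pool))
  if (is.null(pairs) || nrow(pairs) == 0) return(out)
  uq <- unique(queries)
  up <- unique(pool)
  qs <- uq[pairs$q]
  ps <- up[pairs$p]
  ok <- qs != ps & levenshtein(qs, ps) <= 1L
  hit_q <- unique(qs[ok])
  queries %in% hit_q
}

#' Build an amino-acid similarity network of abundant clonotypes
#'
#' Nodes are the repertoire's amino-acid clonotypes with frequency at or
#' above `freq_threshold` (rare clones below 0.001 are excluded from network
#' analysis by default); edges join pairs at Levenshtein distance exactly 1.
#'
#' @param rep a productive-filtered [repertoire()].
#' @param freq_threshold minimum amino-acid clonotype frequency for a node
#'   (default 0.001; a clonotype exactly at the threshold is included).
#' @param new_aa optional character vector of amino-acid sequences to flag as
#'   new (sets the `is_new` vertex attribute).
#' @return an [igraph::graph] with vertex attributes `name` (aa sequence),
#'   `freq` and `is_new`. A repertoire with no clonotype above the threshold
#'   yields an empty graph with a warning.
#' @export
build_network <- function(rep, freq_threshold = 0.001, new_aa = character(0)) {
  stopifnot(is_repertoire(rep), freq_threshold > 0)
  aa <- aa_clonotypes(rep)
  keep <- aa[aa$freq >= freq_threshold, , drop = FALSE]
  if (nrow(keep) == 0) {
    warning("no clonotypes at or above frequency ", freq_threshold,
            " in sample '", rep$sample_id, "'; returning an empty network",
            call. = FALSE)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  verts <- data.frame(name = keep$aa_seq, freq = keep$freq,
                      is_new = keep$aa_seq %in% new_aa)
  if (nrow(keep) > 1) {
    dmat <- utils::adist(keep$aa_seq)
    idx <- which(dmat == 1 & upper.tri(dmat), arr.ind = TRUE)
    edges <- data.frame(from = keep$aa_seq[idx[, 1]], to = keep$aa_seq[idx[, 2]])
  } else {
    edges <- data.frame(from = character(0), to = character(0))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Export a similarity network as edge-list and node-attribute TSVs
#'
#' @param net a network from [build_network()].
#' @param prefix output path prefix; writes `<prefix>_edges.tsv`
#'   (`node1`, `node2`) and `<prefix>_nodes.tsv` (`aa_seq`, `freq`, `is_new`).
#' @return the two paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  edges_path <- paste0(prefix, "_edges.tsv")
  nodes_path <- paste0(prefix, "_nodes.tsv")
  el <- igraph::as_edgelist(net)
  readr::write_tsv(tibble::tibble(node1 = el[, 1], node2 = el[, 2]),
                   edges_path, progress = FALSE)
  if (igraph::vcount(net) > 0) {
    nodes <- tibble::tibble(aa_seq = igraph::V(net)$name,
                            freq = igraph::V(net)$freq,
                            is_new = igraph::V(net)$is_new)
  } else {
    nodes <- tibble::tibble(aa_seq = character(0), freq = numeric(0),
                            is_new = logical(0))
  }
  readr::write_tsv(nodes, nodes_path, progress = FALSE)
  invisible(c(edges_path, nodes_path))
}
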