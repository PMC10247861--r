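#' @title Graph substrate
#'
#' @description Graphs are plain undirected [igraph][igraph::igraph-package]
#' objects: simple (no loops or multi-edges), unweighted, vertices indexed
#' `1..N`. The helpers here cover degree summaries, edge removal, complements,
#' the cycle-partition construction of `(N-3)`-regular input graphs,
#' isomorphism keys, and graph6 / edge-list I/O.
#' @name graph_core
NULL

# dense 0/1 adjacency matrix of an igraph object
adj_matrix <- function(g) {
  A <- igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE)
  dimnames(A) <- NULL
  storage.mode(A) <- "double"
  A
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

check_graph <- function(g) {
  if (!igraph::is_igraph(g)) abort("`g` must be an igraph object")
  if (igraph::is_directed(g)) abort("`g` must be undirected")
  if (igraph::any_multiple(g) || any(igraph::which_loop(g)))
    abort("`g` must be simple (no loops or multi-edges)")
  invisible(g)
}

#' Vertex degrees and degree summary
#'
#' @param g An undirected simple igraph object.
#' @return A list with `k` (per-vertex degrees), `k_max` (maximum degree
#'   \eqn{\Delta(G)}), `k_min` (minimum degree \eqn{\delta(G)}) and `k_mean`
#'   (mean degree \eqn{\bar k}).
#' @examples
#' graph_degrees(igraph::make_full_graph(4))
#' @export
graph_degrees <- function(g) {
  check_graph(g)
  k <- igraph::degree(g)
  list(k = as.numeric(k), k_max = max(k), k_min = min(k), k_mean = mean(k))
}

#' Is the graph connected?
#'
#' Exact traversal-based test (no spectral tolerance involved).
#' @inheritParams graph_degrees
#' @return `TRUE` iff one component spans all vertices.
#' @export
is_connected_graph <- function(g) {
  check_graph(g)
  igraph::is_connected(g)
}

#' Remove a single edge, preserving vertex labels
#'
#' @inheritParams graph_degrees
#' @param i,j Vertex indices (1-based) of an existing edge.
#' @return The graph with edge `(i, j)` removed; no vertex relabeling.
#' @export
remove_edge <- function(g, i, j) {
  check_graph(g)
  eid <- igraph::get_edge_ids(g, c(i, j))
  if (eid == 0) abort(sprintf("edge (%d, %d) is not present", i, j))
  igraph::delete_edges(g, eid)
}

#' Graph complement
#'
#' @inheritParams graph_degrees
#' @return The simple complement (no self-loops).
#' @export
graph_complement <- function(g) {
  check_graph(g)
  igraph::complementer(g)
}

# partitions of n into parts >= 3, each partition non-increasing,
# ordered lexicographically on the sorted parts
cycle_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  if (n < 3) return(list())
  out <- list()
  for (p in seq(min(n, max_part), 3)) {
    rest <- cycle_partitions(n - p, p)
    out <- c(out, lapply(rest, function(r) c(p, r)))
  }
  out
}

#' All (n-3)-regular graphs built from cycle partitions
#'
#' For every partition of `n` into cycle lengths of at least 3, the complement
#' of the disjoint union of those cycles is an `(n-3)`-regular graph; distinct
#' cycle-type multisets give pairwise non-isomorphic complements. Only
#' connected results are returned, ordered lexicographically by the sorted
#' partition (a deterministic campaign order).
#'
#' @param n Number of vertices, at least 6.
#' @return A named list of igraph objects; names encode the partition, e.g.
#'   `"8+3"`.
#' @examples
#' length(regulars_from_cycle_partitions(11)) # 6
#' @export
regulars_from_cycle_partitions <- function(n) {
  if (n < 6) abort("`n` must be at least 6")
  parts <- cycle_partitions(n)
  ord <- order(vapply(parts, function(p) paste(sprintf("%03d", p), collapse = ","),
                      character(1)))
  parts <- parts[ord]
  out <- list()
  for (p in parts) {
    cyc <- igraph::disjoint_union(lapply(p, igraph::make_ring))
    g <- igraph::complementer(cyc)
    if (igraph::is_connected(g)) {
      out[[paste(p, collapse = "+")]] <- g
    }
  }
  out
}

#' Canonical isomorphism key
#'
#' Canonically labels the graph (BLISS) and serializes it as a graph6 string,
#' so two graphs get identical keys iff they are isomorphic.
#' @inheritParams graph_degrees
#' @return A character scalar.
#' @export
canonical_key <- function(g) {
  check_graph(g)
  perm <- igraph::canonical_permutation(g)$labeling
  encode_graph6(adj_matrix(igraph::permute(g, perm)))
}

#' Cospectral key (normalized-Laplacian spectrum)
#'
#' The sorted normalized-Laplacian spectrum rounded to `decimals` places,
#' serialized to text. Isomorphic graphs always share a key; distinct graphs
#' almost always differ (cospectral mates are the rare exception), which makes
#' this the cheap isomorphism proxy used during the search.
#'
#' @inheritParams graph_degrees
#' @param decimals Rounding applied to the eigenvalues before serialization.
#'   The default 9 sits well above eigensolver noise (~1e-12 at these sizes)
#'   and below genuine spectral gaps.
#' @return A character scalar.
#' @export
cospectral_key <- function(g, decimals = 9) {
  check_graph(g)
  lam <- cpp_lap_spectra(adj_matrix(g))$lam
  spectrum_key(lam, decimals)
}

spectrum_key <- function(lam, decimals = 9) {
  vals <- round(sort(lam), decimals) + 0 # + 0 turns -0 into +0
  paste(sprintf("%.*f", decimals, vals), collapse = ",")
}

## --- graph6 codec (nauty dialect, no header) -------------------------------

encode_graph6 <- function(A) {
  n <- nrow(A)
  if (n > 258047) abort("graph6 encoding supported up to n = 258047")
  head <- if (n <= 62) {
    rawToChar(as.raw(n + 63))
  } else {
    rawToChar(as.raw(c(126,
                       bitwAnd(bitwShiftR(n, 12), 63) + 63,
                       bitwAnd(bitwShiftR(n, 6), 63) + 63,
                       bitwAnd(n, 63) + 63)))
  }
  if (n < 2) return(head)
  bits <- unlist(lapply(2:n, function(j) A[seq_len(j - 1), j]))
  pad <- (-length(bits)) %% 6
  bits <- c(bits, rep(0, pad))
  groups <- matrix(bits, nrow = 6)
  vals <- as.integer(c(32, 16, 8, 4, 2, 1) %*% groups)
  paste0(head, rawToChar(as.raw(vals + 63)))
}

decode_graph6 <- function(s) {
  v <- as.integer(charToRaw(s))
  if (length(v) == 0) abort("empty graph6 record")
  if (any(v < 63 | v > 126)) abort("invalid graph6 character")
  if (v[1] == 126) {
    if (length(v) < 4 || v[2] == 126)
      abort("unsupported or truncated graph6 size header")
    n <- bitwShiftL(v[2] - 63, 12) + bitwShiftL(v[3] - 63, 6) + (v[4] - 63)
    v <- v[-(1:4)]
  } else {
    n <- v[1] - 63
    v <- v[-1]
  }
  nbits <- if (n < 2) 0 else n * (n - 1) / 2
  if (length(v) != ceiling(nbits / 6))
    abort("graph6 record has wrong length for its vertex count")
  A <- matrix(0, n, n)
  if (nbits > 0) {
    bits <- as.integer(sapply(v - 63, function(x)
      bitwAnd(bitwShiftR(x, 5:0), 1L)))
    bits <- bits[seq_len(nbits)]
    idx <- 0
    for (j in 2:n) {
      A[seq_len(j - 1), j] <- bits[idx + seq_len(j - 1)]
      idx <- idx + j - 1
    }
    A <- A + t(A)
  }
  A
}

#' Read and write graph6 files
#'
#' One graph per line, nauty dialect without a header line. Round-trips
#' preserve the adjacency exactly (no relabeling).
#'
#' @param path File path.
#' @return `read_graph6()`: a list of igraph objects.
#' @export
read_graph6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    A <- tryCatch(decode_graph6(lines[[i]]), error = function(e)
      abort(sprintf("malformed graph6 record at line %d: %s", i,
                    conditionMessage(e))))
    out[[i]] <- graph_from_adj(A)
  }
  out
}

#' @rdname read_graph6
#' @param graphs A list of igraph objects (or a single one).
#' @export
write_graph6 <- function(graphs, path) {
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  writeLines(vapply(graphs, function(g) encode_graph6(adj_matrix(g)),
                    character(1)), path)
  invisible(path)
}

#' Read and write plain-text edge lists
#'
#' One `"i j"` pair per line, 0-based on disk (in memory vertices are
#' 1-based). `n` may exceed the largest endpoint to allow isolated vertices.
#'
#' @param path File path.
#' @param n Number of vertices; defaults to `max(endpoint) + 1`.
#' @return `read_edgelist()`: an igraph object.
#' @export
read_edgelist <- function(path, n = NULL) {
  el <- as.matrix(utils::read.table(path, col.names = c("i", "j")))
  if (is.null(n)) n <- max(el) + 1
  igraph::graph_from_edgelist(el + 1, directed = FALSE) |>
    igraph::add_vertices(max(0, n - max(el) - 1))
}

#' @rdname read_edgelist
#' @param g An igraph object.
#' @export
write_edgelist <- function(g, path) {
  check_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE) - 1
  utils::write.table(el, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Enumerate connected k-regular graphs (small orders)
#'
#' Exhaustive backtracking over labeled graphs (vertices completed in index
#' order, partners always higher-indexed), followed by isomorphism reduction
#' via cospectral keys refined by canonical keys. Intended for small orders
#' (roughly `n <= 10`); the cycle-partition construction covers `k = n - 3`
#' at larger orders.
#'
#' @param n Number of vertices.
#' @param k Degree (`n * k` must be even, `3 <= k < n`).
#' @return A list of pairwise non-isomorphic connected k-regular igraph
#'   objects.
#' @export
enumerate_regulars <- function(n, k) {
  if ((n * k) %% 2 != 0) abort("n * k must be even")
  if (k < 2 || k >= n) abort("need 2 <= k < n")
  found <- list()
  A <- matrix(0, n, n)
  rem <- rep(k, n)
  recurse <- function() {
    open <- which(rem > 0)
    if (length(open) == 0) {
      if (cpp_connected(A)) found[[length(found) + 1]] <<- A
      return(invisible())
    }
    i <- open[1]
    cand <- open[open > i & A[i, open] == 0]
    need <- rem[i]
    if (length(cand) < need) return(invisible())
    choices <- if (length(cand) == need) list(cand)
               else utils::combn(cand, need, simplify = FALSE)
    for (sel in choices) {
      A[i, sel] <<- 1; A[sel, i] <<- 1
      rem[i] <<- 0; rem[sel] <<- rem[sel] - 1
      recurse()
      A[i, sel] <<- 0; A[sel, i] <<- 0
      rem[i] <<- need; rem[sel] <<- rem[sel] + 1
    }
    invisible()
  }
  recurse()
  if (length(found) == 0) return(list())
  graphs <- lapply(found, graph_from_adj)
  ckeys <- vapply(graphs, cospectral_key, character(1))
  out <- list()
  seen_canon <- character(0)
  for (grp in split(seq_along(graphs), ckeys)) {
    if (length(grp) == 1) {
      out[[length(out) + 1]] <- graphs[[grp]]
    } else {
      keys <- vapply(graphs[grp], canonical_key, character(1))
      for (i in grp[!duplicated(keys)]) out[[length(out) + 1]] <- graphs[[i]]
    }
  }
  out
}
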