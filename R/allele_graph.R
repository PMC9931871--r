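#' Allele graphs
#'
#' An allele graph is a finite simple directed graph whose vertices are the
#' possible allelic states of one genetic locus and whose arrows are the
#' permitted single-step mutations between them. The genotype space over
#' `L` loci is the `L`-fold Cartesian power of this graph; all analytic
#' quantities in the package are computed from the allele graph's adjacency
#' matrix alone.
#'
#' Vertices are kept in lexicographic label order, fixed at construction; all
#' matrices produced by the package use this ordering. Undirected edges are
#' expanded into a pair of opposing arrows.
#'
#' @param adjacency square 0/1 matrix; entry `(v, w) = 1` iff the arrow
#'   `v -> w` exists. The diagonal must be zero (no self-loops).
#' @param labels character vector of vertex names. Defaults to the dimnames
#'   of `adjacency`, or `"a01", "a02", ...` when absent.
#' @param sort_labels reorder vertices lexicographically by label
#'   (default `TRUE`).
#'
#' @return An object of class `allele_graph` with fields `labels`,
#'   `adjacency` (0/1 integer matrix with dimnames), `n` (vertex count) and
#'   `max_degree` (largest in- or out-degree).
#' @examples
#' g <- allele_graph(matrix(c(0, 1, 1, 0), 2, 2), labels = c("x", "y"))
#' g$max_degree
#' @export
allele_graph <- function(adjacency, labels = NULL, sort_labels = TRUE) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    abort("`adjacency` must be a square matrix.", class = "accperc_invalid_graph")
  }
  n <- nrow(adjacency)
  if (is.null(labels)) {
    labels <- rownames(adjacency)
  }
  if (is.null(labels)) {
    labels <- sprintf("a%02d", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels) > 0) {
    abort("`labels` must name every vertex uniquely.",
          class = "accperc_invalid_graph")
  }
  if (!all(adjacency %in% c(0, 1))) {
    abort("`adjacency` entries must be 0 or 1.", class = "accperc_invalid_graph")
  }
  if (any(diag(adjacency) != 0)) {
    abort("self-loops are not allowed in an allele graph.",
          class = "accperc_invalid_graph")
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(labels, labels)
  if (sort_labels) {
    ord <- order(labels, method = "radix")
    adjacency <- adjacency[ord, ord, drop = FALSE]
    labels <- labels[ord]
  }
  structure(
    list(
      labels = labels,
      adjacency = adjacency,
      n = n,
      max_degree = max(0L, rowSums(adjacency), colSums(adjacency))
    ),
    class = "allele_graph"
  )
}

#' @export
print.allele_graph <- function(x, ...) {
  cat(sprintf("<allele_graph: %d vertices, %d arrows, max degree %d>\n",
              x$n, sum(x$adjacency), x$max_degree))
  cat("vertices:", paste(head(x$labels, 10), collapse = ", "),
      if (x$n > 10) "..." else "", "\n")
  invisible(x)
}

is_allele_graph <- function(x) inherits(x, "allele_graph")

assert_graph <- function(graph) {
  if (!is_allele_graph(graph)) {
    abort("expected an `allele_graph` object.", class = "accperc_invalid_graph")
  }
  invisible(graph)
}

#' Resolve a vertex reference (label or index) to an index
#' @noRd
vertex_index <- function(graph, v) {
  if (is.character(v)) {
    idx <- match(v, graph$labels)
  } else {
    idx <- as.integer(v)
    idx[idx < 1L | idx > graph$n] <- NA_integer_
  }
  if (anyNA(idx)) {
    abort(sprintf("unknown vertex: %s",
                  paste(v[is.na(idx)], collapse = ", ")),
          class = "accperc_unknown_vertex")
  }
  idx
}

#' Complete, no-return and path allele graphs
#'
#' `graph_complete()` connects every ordered pair of distinct alleles
#' (mutational free-for-all; the genotype space is a Hamming graph).
#' `graph_complete_no_return()` removes all arrows *into* the wild-type
#' allele, so a locus that has left the wild-type state can never revert; for
#' `n = 2` this is the directed hypercube construction.
#' `graph_path()` chains the alleles `1 - 2 - ... - n` with bidirectional
#' arrows only between neighbours, the minimally connected (worst-case)
#' mutational structure.
#'
#' @param n number of alleles (at least 2).
#' @param wildtype vertex (label or index, default first) whose incoming
#'   arrows are removed.
#' @return An [allele_graph()].
#' @examples
#' graph_complete(4)
#' graph_complete_no_return(2)$adjacency
#' graph_path(3)$adjacency
#' @export
graph_complete <- function(n) {
  n <- check_allele_count(n)
  adj <- matrix(1L, n, n) - diag(1L, n)
  allele_graph(adj, labels = default_labels(n))
}

#' @rdname graph_complete
#' @export
graph_complete_no_return <- function(n, wildtype = 1) {
  n <- check_allele_count(n)
  g <- graph_complete(n)
  wt <- vertex_index(g, if (is.numeric(wildtype)) wildtype else wildtype)
  adj <- g$adjacency
  adj[, wt] <- 0L
  allele_graph(adj, labels = g$labels)
}

#' @rdname graph_complete
#' @export
graph_path <- function(n) {
  n <- check_allele_count(n)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    adj[i, i + 1] <- 1L
    adj[i + 1, i] <- 1L
  }
  allele_graph(adj, labels = default_labels(n))
}

check_allele_count <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) {
    abort("allele count `n` must be a single integer >= 2.",
          class = "accperc_invalid_size")
  }
  n
}

default_labels <- function(n) sprintf("a%02d", 0:(n - 1L))

#' Graph distance between two alleles
#'
#' Length of the shortest directed path on the allele graph, computed via
#' igraph. `Inf` when no path exists.
#'
#' @param graph an [allele_graph()].
#' @param v,w vertex labels or indices.
#' @return a non-negative number (possibly `Inf`).
#' @export
allele_distance <- function(graph, v, w) {
  assert_graph(graph)
  ig <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "directed")
  vi <- vertex_index(graph, v)
  wi <- vertex_index(graph, w)
  as.numeric(igraph::distances(ig, v = vi, to = wi, mode = "out"))
}

#' Structural reachability by walks of non-zero length
#'
#' Boolean matrix with entry `(v, w)` `TRUE` iff a directed walk of length at
#' least 1 leads from `v` to `w`. Used to decide where the matrix-exponential
#' entries (and hence the Gamma functions) are structurally zero.
#' @noRd
reachability_matrix <- function(graph) {
  A <- graph$adjacency != 0L
  reach <- A
  step <- A
  for (k in seq_len(graph$n)) {
    step <- (step %*% (graph$adjacency != 0L)) > 0
    new <- reach | step
    if (identical(new, reach)) break
    reach <- new
  }
  reach
}

#' Genotype pairs and allele counting matrices
#'
#' A genotype is a length-`L` sequence of alleles; a genotype pair fixes the
#' start and end point of the accessibility question. The allele counting
#' matrix `M` of a pair counts, for every ordered allele pair `(v, w)`, the
#' number of loci on which the path must move from `v` to `w`; it divides out
#' the locus-permutation symmetry of the Cartesian power space and (divided
#' by `L`) converges to the divergence matrix in well-behaved setups.
#'
#' @param a,b genotypes given as vectors of allele labels or 1-based indices,
#'   equal length.
#' @return `genotype_pair()` returns an object of class `genotype_pair`
#'   (fields `a`, `b`, `L`); `counting_matrix()` returns an integer matrix
#'   with dimnames taken from the graph and entries summing to `L`.
#' @examples
#' g <- graph_complete(2)
#' counting_matrix(genotype_pair(c(1, 1), c(2, 2)), g)
#' @export
genotype_pair <- function(a, b) {
  if (length(a) != length(b)) {
    abort("genotypes `a` and `b` must have equal length.",
          class = "accperc_length_mismatch")
  }
  if (length(a) == 0L) {
    abort("genotypes must have at least one locus.",
          class = "accperc_length_mismatch")
  }
  structure(list(a = a, b = b, L = length(a)), class = "genotype_pair")
}

#' @rdname genotype_pair
#' @param pair a [genotype_pair()].
#' @param graph an [allele_graph()] supplying the allele alphabet.
#' @export
counting_matrix <- function(pair, graph) {
  assert_graph(graph)
  stopifnot(inherits(pair, "genotype_pair"))
  ai <- vertex_index(graph, pair$a)
  bi <- vertex_index(graph, pair$b)
  M <- matrix(0L, graph$n, graph$n,
              dimnames = list(graph$labels, graph$labels))
  for (l in seq_len(pair$L)) {
    M[ai[l], bi[l]] <- M[ai[l], bi[l]] + 1L
  }
  M
}
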