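# random small allele graphs / setups used across property-style tests

random_digraph <- function(n, p_edge = 0.6) {
  repeat {
    adj <- matrix(rbinom(n * n, 1, p_edge), n, n)
    diag(adj) <- 0L
    g <- allele_graph(adj)
    reach <- getFromNamespace("reachability_matrix", "accperc")(g)
    if (reach[1, n]) return(g)
  }
}

random_small_setup <- function(n = 3, L = 2) {
  g <- random_digraph(n)
  pair <- genotype_pair(rep(1L, L), rep(n, L))
  list(graph = g, pair = pair)
}

relabel_graph <- function(graph, perm) {
  adj <- graph$adjacency[perm, perm]
  dimnames(adj) <- list(graph$labels, graph$labels)
  allele_graph(adj, labels = graph$labels, sort_labels = FALSE)
}

# one irregular order-4 digraph (endpoint pair: vertex 1 -> vertex 4) found by
# exhaustive enumeration; used as the documented irregular fixture
irregular_order4_adjacency <- function() {
  matrix(c(0, 1, 1, 0,
           1, 0, 1, 1,
           1, 1, 0, 0,
           1, 1, 1, 0), 4, 4, byrow = TRUE)
}
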