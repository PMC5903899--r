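# Small network builders shared across test files.

# Directed graph from a two-column character matrix of edges.
net_from_edges <- function(...) {
  edges <- rbind(...)
  igraph::graph_from_edgelist(edges, directed = TRUE)
}

# Sparse random simple digraph with character node names.
rand_digraph <- function(n, p) {
  g <- igraph::sample_gnp(n, p, directed = TRUE, loops = FALSE)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# A single FFL on named nodes.
ffl_net <- function(a = "a", b = "b", c = "c") {
  net_from_edges(c(a, b), c(a, c), c(b, c))
}
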