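# Shared fixtures built in code.

# Random simple digraph adjacency with m edges, current RNG state.
random_adjacency <- function(n, m) {
  cells <- sample(which(row(diag(n)) != col(diag(n))), m)
  adj <- matrix(0L, n, n)
  adj[cells] <- 1L
  adj
}

# Perfect matching of reciprocally connected node pairs.
dyad_graph <- function(n_pairs) {
  n <- 2L * n_pairs
  adj <- matrix(0L, n, n)
  for (k in seq_len(n_pairs)) {
    i <- 2L * k - 1L
    adj[i, i + 1L] <- 1L
    adj[i + 1L, i] <- 1L
  }
  bdgraph(adj)
}

# Random band-energy distribution rows.
random_distributions <- function(n) {
  m <- matrix(stats::rgamma(n * 5, 1), n, 5)
  m / rowSums(m)
}

# Bidirectional star graph: centre node 1 linked both ways with every leaf.
star_graph <- function(n_leaves) {
  n <- n_leaves + 1L
  adj <- matrix(0L, n, n)
  adj[1, 2:n] <- 1L
  adj[2:n, 1] <- 1L
  bdgraph(adj)
}

directed_cycle <- function(n) {
  adj <- matrix(0L, n, n)
  adj[cbind(seq_len(n), c(2:n, 1L))] <- 1L
  bdgraph(adj)
}
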