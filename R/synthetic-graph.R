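# Ground-truth coupling graphs for the synthetic-data generator.

ring_lattice_adjacency <- function(n_nodes, k) {
  assert_that(k %% 2 == 0 && k >= 2, "lattice mean degree k must be even >= 2")
  assert_that(k < n_nodes, "k must be smaller than n_nodes")
  adj <- matrix(0L, n_nodes, n_nodes)
  for (d in seq_len(k %/% 2)) {
    fw <- cbind(seq_len(n_nodes), (seq_len(n_nodes) + d - 1L) %% n_nodes + 1L)
    bw <- cbind(seq_len(n_nodes), (seq_len(n_nodes) - d - 1L) %% n_nodes + 1L)
    adj[fw] <- 1L
    adj[bw] <- 1L
  }
  adj
}

rewire_targets <- function(adj, p_rewire) {
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in which(adj[i, ] == 1L)) {
      if (stats::runif(1) < p_rewire) {
        candidates <- which(adj[i, ] == 0L & seq_len(n) != i)
        if (length(candidates) > 0) {
          adj[i, j] <- 0L
          adj[i, sample(candidates, 1L)] <- 1L
        }
      }
    }
  }
  adj
}

#' Generate a ground-truth coupling graph
#'
#' Seed-deterministic construction of the directed graph whose edges define
#' which node pairs are pulled toward a shared band-energy distribution by
#' the signal simulator.
#'
#' Topologies and their parameters:
#' \itemize{
#'   \item \code{"random"}: uniform simple digraph with exactly
#'     \code{n_edges} edges.
#'   \item \code{"lattice"}: directed ring lattice, each node connected both
#'     ways to its \code{k}/2 nearest neighbours per side (exactly
#'     \code{n_nodes * k} edges).
#'   \item \code{"smallworld"}: Watts-Strogatz construction — the ring
#'     lattice with every out-edge target rewired with probability
#'     \code{p_rewire} (edge count preserved).
#'   \item \code{"modular"}: planted partition with \code{n_modules} equal
#'     modules, within-module edge probability \code{p_in}, between-module
#'     \code{p_out}; module ids are stored in \code{$modules}.
#' }
#'
#' @param n_nodes number of nodes (>= 4).
#' @param topology one of "random", "lattice", "smallworld", "modular".
#' @param params named list of topology parameters (see above).
#' @param seed integer seed.
#' @return a \code{bdgraph} with \code{topology}, \code{params} and, for
#'   modular graphs, a \code{modules} element (1-based module id per node).
#' @export
generate_coupling_graph <- function(n_nodes, topology, params, seed = 1L) {
  assert_that(n_nodes >= 4, "need at least 4 nodes")
  topology <- match.arg(topology, c("random", "lattice", "smallworld",
                                    "modular"))
  g <- with_seed(seed, switch(
    topology,
    random = {
      m <- params$n_edges
      assert_that(!is.null(m), "random topology needs params$n_edges")
      assert_that(m >= 1 && m <= n_nodes * (n_nodes - 1),
                  "infeasible edge count %d for %d nodes", m, n_nodes)
      random_directed_gnm(n_nodes, m)
    },
    lattice = {
      assert_that(!is.null(params$k), "lattice topology needs params$k")
      bdgraph(ring_lattice_adjacency(n_nodes, params$k))
    },
    smallworld = {
      assert_that(!is.null(params$k) && !is.null(params$p_rewire),
                  "smallworld topology needs params$k and params$p_rewire")
      adj <- ring_lattice_adjacency(n_nodes, params$k)
      bdgraph(rewire_targets(adj, params$p_rewire))
    },
    modular = {
      nm <- params$n_modules %||% 4L
      p_in <- params$p_in %||% 0.4
      p_out <- params$p_out %||% 0.02
      assert_that(n_nodes %% nm == 0,
                  "n_nodes (%d) must be a multiple of n_modules (%d)",
                  n_nodes, nm)
      modules <- rep(seq_len(nm), each = n_nodes %/% nm)
      same <- outer(modules, modules, "==")
      prob <- ifelse(same, p_in, p_out)
      adj <- matrix(as.integer(stats::runif(n_nodes^2) < prob),
                    n_nodes, n_nodes)
      diag(adj) <- 0L
      gg <- bdgraph(adj)
      gg$modules <- modules
      gg
    }
  ))
  g$topology <- topology
  g$params <- params
  g$seed <- seed
  g
}
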