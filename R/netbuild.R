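# Building binary directed graphs from RWE dissimilarity matrices at fixed
# edge counts.

#' Binary directed graph container
#'
#' @param adjacency square 0/1 matrix with zero diagonal.
#' @param density_label optional label (e.g. the requested edge count).
#' @param topology optional topology label for generated ground-truth graphs.
#' @param params optional topology parameter list.
#' @return a \code{bdgraph}: list with \code{adjacency}, \code{n_nodes},
#'   \code{n_edges} and the optional metadata.
#' @export
bdgraph <- function(adjacency, density_label = NULL, topology = NULL,
                    params = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  assert_that(ncol(adjacency) == n, "adjacency must be square")
  assert_that(all(adjacency %in% c(0, 1)), "adjacency must be binary")
  assert_that(all(diag(adjacency) == 0), "self-loops are not allowed")
  storage.mode(adjacency) <- "integer"
  structure(list(adjacency = adjacency, n_nodes = n,
                 n_edges = sum(adjacency),
                 density_label = density_label,
                 topology = topology, params = params),
            class = "bdgraph")
}

#' @export
print.bdgraph <- function(x, ...) {
  cat(sprintf("<bdgraph> %d nodes, %d directed edges (density %.3f)%s%s\n",
              x$n_nodes, x$n_edges,
              x$n_edges / (x$n_nodes * (x$n_nodes - 1)),
              if (!is.null(x$topology)) paste0(", topology ", x$topology) else "",
              if (!is.null(x$density_label)) paste0(", label ", x$density_label) else ""))
  invisible(x)
}

#' Convert a bdgraph to an igraph object
#'
#' @param g a \code{bdgraph}.
#' @return a directed \code{igraph} graph with the same node order.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "bdgraph"))
  edges <- which(g$adjacency == 1L, arr.ind = TRUE)
  igraph::graph_from_edgelist(
    matrix(c(edges[, 1], edges[, 2]), ncol = 2), directed = TRUE
  ) -> ig
  if (igraph::vcount(ig) < g$n_nodes) {
    ig <- igraph::add_vertices(ig, g$n_nodes - igraph::vcount(ig))
  }
  ig
}

#' Threshold an RWE matrix to a fixed number of edges
#'
#' The \code{n_edges} off-diagonal cells with the smallest RWE values (the
#' most synchronised pairs) become directed edges i -> j. Ties are broken
#' deterministically by (value, source index, target index) lexicographic
#' order, so nested edge counts give nested graphs. Setting
#' \code{strongest = FALSE} connects the most dissimilar pairs instead
#' (sensitivity analysis only).
#'
#' @param m an \code{rwe_matrix} (or plain square numeric matrix).
#' @param n_edges requested edge count, at most \code{n*(n-1)}.
#' @param strongest connect smallest-RWE pairs (default TRUE).
#' @return a \code{bdgraph} with exactly \code{n_edges} edges.
#' @export
threshold_to_density <- function(m, n_edges, strongest = TRUE) {
  m <- unclass(m)
  n <- nrow(m)
  assert_that(ncol(m) == n, "matrix must be square")
  assert_that(!anyNA(m), "RWE matrix contains NaN/NA")
  n_edges <- as.integer(n_edges)
  assert_that(n_edges >= 1 && n_edges <= n * (n - 1),
              "n_edges = %d infeasible for %d nodes (max %d)",
              n_edges, n, n * (n - 1))
  off <- which(row(m) != col(m))
  src <- row(m)[off]
  tgt <- col(m)[off]
  vals <- m[off]
  if (!strongest) vals <- -vals
  ord <- order(vals, src, tgt)
  pick <- off[ord[seq_len(n_edges)]]
  adj <- matrix(0L, n, n)
  adj[pick] <- 1L
  bdgraph(adj, density_label = n_edges)
}

#' Per-epoch graphs for one participant/condition
#'
#' One thresholded graph per epoch RWE matrix; downstream scalar metrics are
#' computed per epoch and averaged per participant.
#'
#' @param epoch_matrices non-empty list of \code{rwe_matrix}.
#' @param n_edges requested edge count.
#' @param strongest see \code{\link{threshold_to_density}}.
#' @return list of \code{bdgraph}, one per epoch.
#' @export
participant_graphs <- function(epoch_matrices, n_edges, strongest = TRUE) {
  assert_that(length(epoch_matrices) >= 1, "no epoch matrices supplied")
  lapply(epoch_matrices, threshold_to_density, n_edges = n_edges,
         strongest = strongest)
}
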