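# Global network characteristics: directed clustering, characteristic path
# length, random null ensembles and the small-world index sigma.

#' Directed clustering coefficient (all-motif generalisation)
#'
#' Fagiolo's directed clustering: with S = A + t(A),
#' \deqn{C_i = (S^3)_{ii} / (2 [d^{tot}_i (d^{tot}_i - 1) - 2 d^{bi}_i])}
#' where \eqn{d^{tot}} is total (in+out) degree and \eqn{d^{bi}} the number
#' of reciprocated neighbours. Reduces to the classic coefficient on
#' symmetric graphs; nodes with fewer than two distinct neighbours get 0.
#'
#' @param g a \code{bdgraph}.
#' @return list with \code{per_node} and \code{mean}.
#' @export
clustering_directed <- function(g) {
  stopifnot(inherits(g, "bdgraph"))
  a <- g$adjacency
  s <- a + t(a)
  storage.mode(s) <- "double"
  num <- diag(s %*% s %*% s)
  d_tot <- rowSums(s)
  d_bi <- rowSums(a * t(a))
  den <- 2 * (d_tot * (d_tot - 1) - 2 * d_bi)
  c_i <- ifelse(den > 0, num / pmax(den, 1e-300), 0)
  list(per_node = as.numeric(c_i), mean = mean(c_i))
}

#' Characteristic path length of a directed graph
#'
#' Mean shortest directed path (in hops) over all reachable ordered node
#' pairs; unreachable pairs are excluded from the mean and reported as a
#' fraction. A harmonic-mean alternative (global efficiency, which keeps
#' unreachable pairs as zero contribution) is available behind a flag.
#'
#' @param g a \code{bdgraph} with at least one edge.
#' @param harmonic if TRUE also report 1 / global efficiency.
#' @return list with \code{l_mean}, \code{unreachable_fraction} and, if
#'   requested, \code{l_harmonic}.
#' @export
characteristic_path_length <- function(g, harmonic = FALSE) {
  stopifnot(inherits(g, "bdgraph"))
  assert_that(g$n_edges > 0, "graph has no edges")
  d <- igraph::distances(as_igraph(g), mode = "out")
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  out <- list(l_mean = mean(off[reach]),
              unreachable_fraction = 1 - mean(reach))
  if (harmonic) out$l_harmonic <- 1 / mean(1 / off)
  out
}

# Uniform simple directed G(n, m) graph with exactly m edges.
random_directed_gnm <- function(n_nodes, n_edges) {
  cells <- sample.int(n_nodes * (n_nodes - 1L), n_edges)
  idx0 <- cells - 1L
  src <- idx0 %/% (n_nodes - 1L)
  off <- idx0 %% (n_nodes - 1L)
  tgt <- off + (off >= src)
  adj <- matrix(0L, n_nodes, n_nodes)
  adj[cbind(src + 1L, tgt + 1L)] <- 1L
  bdgraph(adj, topology = "random", params = list(n_edges = n_edges))
}

#' Ensemble of uniform random directed graphs at fixed density
#'
#' Null model for the small-world index: graphs with the same node and edge
#' counts as the observed network, drawn uniformly among simple directed
#' graphs.
#'
#' @param n_nodes,n_edges graph size.
#' @param n_nulls ensemble size (default 100).
#' @param seed integer seed; the ensemble is deterministic given the seed.
#' @return list of \code{bdgraph}.
#' @export
random_null_ensemble <- function(n_nodes, n_edges, n_nulls = 100L, seed = 1L) {
  assert_that(n_edges >= 1 && n_edges <= n_nodes * (n_nodes - 1),
              "infeasible edge count")
  assert_that(n_nulls >= 1, "need at least one null")
  with_seed(seed, replicate(n_nulls, random_directed_gnm(n_nodes, n_edges),
                            simplify = FALSE))
}

#' Mean clustering and path length of a null ensemble
#'
#' Generates the nulls one at a time (so large ensembles never have to be
#' held in memory) and returns the ensemble means.
#'
#' @param n_nodes,n_edges graph size.
#' @param n_nulls ensemble size (default 100).
#' @param seed integer seed.
#' @return list with \code{c_rand}, \code{l_rand}, \code{n_nulls},
#'   \code{seed}.
#' @export
null_ensemble_stats <- function(n_nodes, n_edges, n_nulls = 100L, seed = 1L) {
  assert_that(n_edges >= 1 && n_edges <= n_nodes * (n_nodes - 1),
              "infeasible edge count")
  cs <- numeric(n_nulls)
  ls <- numeric(n_nulls)
  with_seed(seed, {
    for (i in seq_len(n_nulls)) {
      gr <- random_directed_gnm(n_nodes, n_edges)
      cs[i] <- clustering_directed(gr)$mean
      ls[i] <- characteristic_path_length(gr)$l_mean
    }
  })
  list(c_rand = mean(cs), l_rand = mean(ls), n_nulls = n_nulls, seed = seed)
}

ensemble_stats <- function(ensemble) {
  if (!is.null(ensemble$c_rand)) return(ensemble)
  cs <- vapply(ensemble, function(gr) clustering_directed(gr)$mean, numeric(1))
  ls <- vapply(ensemble, function(gr) characteristic_path_length(gr)$l_mean,
               numeric(1))
  list(c_rand = mean(cs), l_rand = mean(ls), n_nulls = length(ensemble),
       seed = NA_integer_)
}

#' Small-world index sigma against a random null ensemble
#'
#' \deqn{\sigma = (C / C_{rand}) / (L / L_{rand})}
#' with C the mean directed clustering coefficient and L the characteristic
#' path length; \eqn{C_{rand}}, \eqn{L_{rand}} are ensemble means over
#' density-matched random graphs. \eqn{\sigma > 1} indicates above-random
#' clustering with near-random path length.
#'
#' @param g a \code{bdgraph}.
#' @param ensemble a list of null \code{bdgraph}s (see
#'   \code{\link{random_null_ensemble}}) or precomputed stats from
#'   \code{\link{null_ensemble_stats}}.
#' @return a \code{global_metrics}: list with \code{c_mean}, \code{l_mean},
#'   \code{c_rand}, \code{l_rand}, \code{sigma}, \code{n_nulls},
#'   \code{unreachable_fraction}.
#' @export
small_world_sigma <- function(g, ensemble) {
  stopifnot(inherits(g, "bdgraph"))
  ns <- ensemble_stats(ensemble)
  assert_that(ns$c_rand > 0 && ns$l_rand > 0,
              "degenerate null ensemble (zero clustering or path length)")
  cc <- clustering_directed(g)$mean
  pl <- characteristic_path_length(g)
  structure(list(c_mean = cc, l_mean = pl$l_mean,
                 c_rand = ns$c_rand, l_rand = ns$l_rand,
                 sigma = (cc / ns$c_rand) / (pl$l_mean / ns$l_rand),
                 n_nulls = ns$n_nulls,
                 unreachable_fraction = pl$unreachable_fraction),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf(paste0("<global_metrics> C = %.4f (C_rand %.4f), ",
                     "L = %.3f (L_rand %.3f), sigma = %.3f [%d nulls, ",
                     "%.1f%% unreachable pairs]\n"),
              x$c_mean, x$c_rand, x$l_mean, x$l_rand, x$sigma, x$n_nulls,
              100 * x$unreachable_fraction))
  invisible(x)
}
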