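# Local network analysis: betweenness hubs, community structure,
# within-module z-score, participation coefficient, Guimera-Amaral roles.

#' Directed shortest-path betweenness, raw and mean-normalised
#'
#' Exact Brandes-style betweenness on the directed graph (path endpoints
#' excluded), plus the relative value \eqn{B_i = bc_i / mean(bc)} used for
#' hub detection. If every node has zero betweenness all \eqn{B_i} are 0.
#'
#' @param g a \code{bdgraph}.
#' @return data.frame with columns \code{node}, \code{bc_raw}, \code{b_i}.
#' @export
betweenness_nodes <- function(g) {
  stopifnot(inherits(g, "bdgraph"))
  bc <- igraph::betweenness(as_igraph(g), directed = TRUE)
  m <- mean(bc)
  b_i <- if (m > 0) bc / m else rep(0, length(bc))
  data.frame(node = seq_along(bc), bc_raw = as.numeric(bc),
             b_i = as.numeric(b_i))
}

#' Detect hubs from relative betweenness
#'
#' @param b_i numeric vector of mean-normalised betweenness values.
#' @param threshold hub criterion, inclusive (default 1.5).
#' @return integer vector of hub node indices.
#' @export
detect_hubs <- function(b_i, threshold = 1.5) {
  assert_that(threshold > 0, "hub threshold must be positive")
  which(b_i >= threshold)
}

#' Community partition by modularity maximisation
#'
#' Locally greedy (Louvain) modularity optimisation. igraph's implementation
#' is defined for undirected graphs, so the digraph is symmetrised with edge
#' weight equal to the number of directed edges between each pair (1 or 2);
#' the run is seed-deterministic.
#'
#' @param g a \code{bdgraph} with at least one edge.
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed.
#' @return integer vector of 0-based module ids, dense from 0.
#' @export
community_partition <- function(g, gamma = 1, seed = 1L) {
  stopifnot(inherits(g, "bdgraph"))
  assert_that(g$n_edges > 0, "cannot partition an edgeless graph")
  s <- g$adjacency + t(g$adjacency)
  ig <- igraph::graph_from_adjacency_matrix(s, mode = "undirected",
                                            weighted = TRUE)
  cl <- with_seed(seed,
                  igraph::cluster_louvain(ig, resolution = gamma,
                                          weights = igraph::E(ig)$weight))
  mem <- igraph::membership(cl)
  as.integer(match(mem, sort(unique(mem))) - 1L)
}

within_module_degree <- function(g, partition,
                                 mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  a <- g$adjacency
  same <- outer(partition, partition, "==")
  diag(same) <- FALSE
  k_out <- rowSums(a * same)
  k_in <- colSums(a * same)
  switch(mode, total = k_in + k_out, "in" = k_in, out = k_out)
}

#' Within-module degree z-score
#'
#' Standardises each node's within-module degree (in+out by default) against
#' the mean and population standard deviation of its own module; modules
#' with zero spread assign z = 0 to all members.
#'
#' @param g a \code{bdgraph}.
#' @param partition integer module ids covering all nodes.
#' @param mode degree convention: "total" (default), "in" or "out".
#' @return numeric vector of z-scores.
#' @export
within_module_z <- function(g, partition, mode = "total") {
  stopifnot(inherits(g, "bdgraph"))
  assert_that(length(partition) == g$n_nodes,
              "partition must cover all %d nodes", g$n_nodes)
  kappa <- within_module_degree(g, partition, mode)
  z <- numeric(g$n_nodes)
  for (m in unique(partition)) {
    idx <- which(partition == m)
    mu <- mean(kappa[idx])
    sd_pop <- sqrt(mean((kappa[idx] - mu)^2))
    z[idx] <- if (sd_pop > 0) (kappa[idx] - mu) / sd_pop else 0
  }
  z
}

#' Participation coefficient
#'
#' \deqn{P_i = 1 - \sum_m (\kappa_{im} / k_i)^2} with \eqn{\kappa_{im}} the
#' node's (in+out) degree into module m and \eqn{k_i} its total degree;
#' 0 when all edges stay inside one module, approaching 1 when they spread
#' evenly across modules. Isolated nodes get 0.
#'
#' @param g a \code{bdgraph}.
#' @param partition integer module ids covering all nodes.
#' @param mode degree convention: "total" (default), "in" or "out".
#' @return numeric vector in [0, 1].
#' @export
participation_coefficient <- function(g, partition, mode = c("total", "in", "out")) {
  stopifnot(inherits(g, "bdgraph"))
  assert_that(length(partition) == g$n_nodes,
              "partition must cover all %d nodes", g$n_nodes)
  mode <- match.arg(mode)
  a <- g$adjacency
  mods <- sort(unique(partition))
  n <- g$n_nodes
  k_im <- matrix(0, n, length(mods))
  for (j in seq_along(mods)) {
    in_m <- partition == mods[j]
    out_deg <- rowSums(a[, in_m, drop = FALSE])
    in_deg <- colSums(a[in_m, , drop = FALSE])
    k_im[, j] <- switch(mode, total = out_deg + in_deg, "in" = in_deg,
                        out = out_deg)
  }
  k <- rowSums(k_im)
  p <- ifelse(k > 0, 1 - rowSums((k_im / pmax(k, 1))^2), 0)
  pmin(pmax(p, 0), 1)
}

ROLE_LEVELS <- c("ultra-peripheral", "peripheral", "connector non-hub",
                 "kinless non-hub", "provincial hub", "connector hub",
                 "kinless hub")

#' Guimera-Amaral functional cartography role assignment
#'
#' Nodes with within-module z-score >= 1.5 are cartographic hubs. Non-hubs:
#' ultra-peripheral (P <= 0.05), peripheral (0.05 < P <= 0.45), connector
#' (0.45 < P <= 0.70), kinless (P > 0.70). Hubs: provincial (P <= 0.25),
#' connector (0.25 < P <= 0.50), kinless (P > 0.50). The seven roles tile
#' the (z, P) plane exactly.
#'
#' @param z numeric vector of within-module z-scores.
#' @param p numeric vector of participation coefficients in [0, 1].
#' @param z_threshold hub threshold on z (default 1.5, inclusive).
#' @return factor of roles, levels in a fixed order.
#' @export
assign_roles <- function(z, p, z_threshold = 1.5) {
  assert_that(length(z) == length(p), "z and p must have equal length")
  assert_that(all(is.finite(p)) && all(p >= 0 & p <= 1),
              "participation coefficients must lie in [0, 1]")
  hub <- z >= z_threshold
  role <- character(length(z))
  role[!hub & p <= 0.05] <- "ultra-peripheral"
  role[!hub & p > 0.05 & p <= 0.45] <- "peripheral"
  role[!hub & p > 0.45 & p <= 0.70] <- "connector non-hub"
  role[!hub & p > 0.70] <- "kinless non-hub"
  role[hub & p <= 0.25] <- "provincial hub"
  role[hub & p > 0.25 & p <= 0.50] <- "connector hub"
  role[hub & p > 0.50] <- "kinless hub"
  factor(role, levels = ROLE_LEVELS)
}

#' Full per-node metrics table for one graph
#'
#' Betweenness (raw and relative), community membership, within-module
#' z-score, participation coefficient, role, and the two independent hub
#' flags (relative betweenness >= \code{bc_threshold}; cartographic z >=
#' \code{z_threshold}).
#'
#' @param g a \code{bdgraph}.
#' @param gamma community detection resolution.
#' @param seed community detection seed.
#' @param bc_threshold relative-betweenness hub criterion (default 1.5).
#' @param z_threshold cartographic hub criterion (default 1.5).
#' @return data.frame, one row per node.
#' @export
node_metrics <- function(g, gamma = 1, seed = 1L, bc_threshold = 1.5,
                         z_threshold = 1.5) {
  bt <- betweenness_nodes(g)
  part <- community_partition(g, gamma = gamma, seed = seed)
  z <- within_module_z(g, part)
  p <- participation_coefficient(g, part)
  data.frame(
    node = bt$node, bc_raw = bt$bc_raw, b_i = bt$b_i,
    module_id = part, z = z, p = p,
    role = assign_roles(z, p, z_threshold),
    is_hub_bc = bt$b_i >= bc_threshold
  )
}

#' Named node subset (e.g. a resting-state network)
#'
#' @param name subset label (e.g. "DMN").
#' @param node_ids unique 1-based node indices.
#' @return a \code{node_subset}.
#' @export
node_subset <- function(name, node_ids) {
  node_ids <- as.integer(node_ids)
  assert_that(!anyDuplicated(node_ids), "subset node ids must be unique")
  assert_that(length(node_ids) >= 1, "empty subset")
  structure(list(name = name, node_ids = node_ids), class = "node_subset")
}

#' Read node subsets from a two-column delimited file
#'
#' File format: two tab-separated columns (subset name, 0-based node id),
#' with a header line.
#'
#' @param path file path.
#' @return named list of \code{node_subset}.
#' @export
read_node_subsets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "subset file needs two columns (name, node id)")
  sp <- split(df[[2]], df[[1]])
  lapply(stats::setNames(names(sp), names(sp)), function(nm) {
    node_subset(nm, sp[[nm]] + 1L)
  })
}

#' Aggregate node metrics over a subset
#'
#' Means of relative betweenness, participation coefficient and
#' within-module z-score over the subset's nodes (the union of several
#' subsets can be aggregated by passing a combined subset).
#'
#' @param table a node metrics data.frame from \code{\link{node_metrics}}.
#' @param subset a \code{node_subset} with valid node ids.
#' @return one-row data.frame: subset, n_nodes, mean_b_i, mean_p, mean_z.
#' @export
subset_metrics <- function(table, subset) {
  stopifnot(inherits(subset, "node_subset"))
  assert_that(all(subset$node_ids %in% table$node),
              "subset '%s' references nodes outside the table", subset$name)
  rows <- table[table$node %in% subset$node_ids, ]
  data.frame(subset = subset$name, n_nodes = nrow(rows),
             mean_b_i = mean(rows$b_i), mean_p = mean(rows$p),
             mean_z = mean(rows$z))
}
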