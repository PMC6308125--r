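test_that("betweenness identifies star centres and is flat on cycles", {
  st <- star_graph(6)
  bt <- betweenness_nodes(st)
  expect_true(all(bt$bc_raw[-1] == 0))
  expect_gt(bt$b_i[1], 1.5)
  expect_equal(detect_hubs(bt$b_i), 1L)

  cyc <- directed_cycle(8)
  btc <- betweenness_nodes(cyc)
  expect_equal(btc$b_i, rep(1, 8))
  expect_length(detect_hubs(btc$b_i), 0)

  # threshold is inclusive
  expect_equal(detect_hubs(c(1.5, 1.49999, 2)), c(1L, 3L))

  # edgeless graph: zero everywhere, no division by the zero mean
  bz <- betweenness_nodes(bdgraph(matrix(0L, 4, 4)))
  expect_equal(bz$b_i, rep(0, 4))
})

test_that("betweenness matches exhaustive path enumeration", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    m <- sample(n:min(20, n * (n - 1)), 1)
    adj <- random_adjacency(n, m)
    got <- betweenness_nodes(bdgraph(adj))$bc_raw
    expect_equal(got, oracle_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("community detection recovers planted structure deterministically", {
  # two complete components are two modules
  two <- matrix(0L, 20, 20)
  two[1:10, 1:10] <- 1L; two[11:20, 11:20] <- 1L; diag(two) <- 0L
  part <- community_partition(bdgraph(two), seed = 1)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[1:10])), 1)
  expect_equal(length(unique(part[11:20])), 1)
  expect_identical(sort(unique(part)), c(0L, 1L))

  # planted 4-module graphs: adjusted agreement >= 0.9 across 20 seeds
  ari <- vapply(1:20, function(s) {
    g <- generate_coupling_graph(48, "modular",
                                 list(n_modules = 4, p_in = 0.5, p_out = 0.02),
                                 seed = s)
    part <- community_partition(g, seed = s)
    igraph::compare(part + 1L, g$modules, method = "adjusted.rand")
  }, numeric(1))
  expect_gte(mean(ari), 0.9)

  g <- generate_coupling_graph(30, "random", list(n_edges = 120), seed = 2)
  expect_identical(community_partition(g, seed = 5),
                   community_partition(g, seed = 5))
  expect_error(community_partition(bdgraph(matrix(0L, 3, 3))), "edgeless")
})

test_that("within-module z-score standardises within-module degree", {
  # module with equal degrees: z = 0 everywhere
  two <- matrix(0L, 6, 6)
  two[1:3, 1:3] <- 1L; two[4:6, 4:6] <- 1L; diag(two) <- 0L
  g <- bdgraph(two)
  part <- c(0L, 0L, 0L, 1L, 1L, 1L)
  expect_equal(within_module_z(g, part), rep(0, 6))

  # hand-computed 8-node toy: node 1 holds every within-module tie
  adj <- matrix(0L, 8, 8)
  adj[1, 2:4] <- 1L; adj[2:4, 1] <- 1L      # module 0: star around node 1
  adj[5, 6] <- 1L; adj[6, 5] <- 1L          # module 1: one dyad + 2 isolates
  g2 <- bdgraph(adj)
  part2 <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  z <- within_module_z(g2, part2)
  # module 0 kappas: (6, 2, 2, 2) -> mean 3, pop sd sqrt(3)
  expect_equal(z[1], 3 / sqrt(3), tolerance = 1e-12)
  expect_equal(z[2:4], rep(-1 / sqrt(3), 3), tolerance = 1e-12)
  # module 1 kappas: (2, 2, 0, 0) -> mean 1, pop sd 1
  expect_equal(z[5:8], c(1, 1, -1, -1), tolerance = 1e-12)
  expect_equal(which.max(z), 1L)
})

test_that("participation coefficient follows the degree split", {
  # all edges inside the node's own module
  two <- matrix(0L, 6, 6)
  two[1:3, 1:3] <- 1L; two[4:6, 4:6] <- 1L; diag(two) <- 0L
  part <- c(0L, 0L, 0L, 1L, 1L, 1L)
  expect_equal(participation_coefficient(bdgraph(two), part), rep(0, 6))

  # node 1: degree split equally across 2 modules -> 0.5
  adj <- matrix(0L, 5, 5)
  adj[1, 2] <- 1L; adj[1, 3] <- 1L
  p <- participation_coefficient(bdgraph(adj), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(p[1], 0.5)

  # degree split equally across 4 modules -> 0.75
  adj4 <- matrix(0L, 5, 5)
  adj4[1, 2:5] <- 1L
  p4 <- participation_coefficient(bdgraph(adj4), c(0L, 0L, 1L, 2L, 3L))
  expect_equal(p4[1], 0.75)

  # bounds and the single-module degenerate case
  set.seed(52)
  g <- bdgraph(random_adjacency(15, 60))
  pr <- participation_coefficient(g, rep(0L, 15))
  expect_equal(pr, rep(0, 15))
  pr2 <- participation_coefficient(g, sample(0:2, 15, replace = TRUE))
  expect_true(all(pr2 >= 0 & pr2 <= 1))
})

test_that("role assignment uses the printed thresholds inclusively", {
  expect_equal(as.character(assign_roles(2.0, 0.10)), "provincial hub")
  expect_equal(as.character(assign_roles(1.5, 0.60)), "kinless hub")
  expect_equal(as.character(assign_roles(0.0, 0.03)), "ultra-peripheral")
  expect_equal(as.character(assign_roles(1.49999, 0.60)), "connector non-hub")
  expect_equal(as.character(assign_roles(1.5, 0.25)), "provincial hub")
  expect_equal(as.character(assign_roles(-1, 0.45)), "peripheral")
  expect_error(assign_roles(0, 1.2), "\\[0, 1\\]")
})

test_that("subset aggregation averages the right rows", {
  set.seed(53)
  g <- bdgraph(random_adjacency(20, 80))
  tab <- node_metrics(g, seed = 3)
  all_sub <- subset_metrics(tab, node_subset("all", 1:20))
  expect_equal(all_sub$mean_b_i, mean(tab$b_i))
  expect_equal(all_sub$mean_p, mean(tab$p))
  expect_equal(all_sub$mean_z, mean(tab$z))

  one <- subset_metrics(tab, node_subset("solo", 7L))
  expect_equal(one$mean_p, tab$p[7])
  expect_error(subset_metrics(tab, node_subset("bad", c(3L, 99L))),
               "outside")

  # the bundled synthetic resting-state subsets load and aggregate
  subs <- read_node_subsets(system.file("extdata", "synthetic_subsets.tsv",
                                        package = "rweconn"))
  expect_setequal(names(subs), c("DMN", "FPN", "EN"))
  g64 <- generate_coupling_graph(64, "modular",
                                 list(n_modules = 4, p_in = 0.4, p_out = 0.05),
                                 seed = 9)
  tab64 <- node_metrics(g64, seed = 9)
  res <- do.call(rbind, lapply(subs, function(s) subset_metrics(tab64, s)))
  expect_equal(nrow(res), 3)
  combo <- node_subset("union", sort(unique(unlist(lapply(subs, `[[`,
                                                          "node_ids")))))
  expect_equal(subset_metrics(tab64, combo)$n_nodes, length(combo$node_ids))
})
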