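test_that("coupling graphs honour their topology contracts", {
  # 12 edges on 4 nodes is every possible directed edge
  g <- generate_coupling_graph(4, "random", list(n_edges = 12), seed = 1)
  expect_equal(g$adjacency, matrix(1L, 4, 4) - diag(4L), ignore_attr = TRUE)

  # seed determinism
  g1 <- generate_coupling_graph(40, "random", list(n_edges = 100), seed = 3)
  g2 <- generate_coupling_graph(40, "random", list(n_edges = 100), seed = 3)
  expect_identical(g1$adjacency, g2$adjacency)
  g3 <- generate_coupling_graph(40, "random", list(n_edges = 100), seed = 4)
  expect_false(identical(g3$adjacency, g1$adjacency))

  # lattice and smallworld keep the exact edge count, no self-loops
  lat <- generate_coupling_graph(30, "lattice", list(k = 6), seed = 1)
  expect_equal(lat$n_edges, 180L)
  sw <- generate_coupling_graph(30, "smallworld",
                                list(k = 6, p_rewire = 0.2), seed = 5)
  expect_equal(sw$n_edges, 180L)
  expect_true(all(diag(sw$adjacency) == 0))
  expect_identical(sw$adjacency,
                   generate_coupling_graph(30, "smallworld",
                                           list(k = 6, p_rewire = 0.2),
                                           seed = 5)$adjacency)

  mod <- generate_coupling_graph(16, "modular",
                                 list(n_modules = 4, p_in = 0.9,
                                      p_out = 0.01), seed = 2)
  expect_equal(mod$modules, rep(1:4, each = 4))

  expect_error(generate_coupling_graph(4, "banana", list(), 1))
  expect_error(generate_coupling_graph(4, "random", list(n_edges = 13), 1),
               "infeasible")
})

test_that("simulated recordings are reproducible and correctly scaled", {
  g <- generate_coupling_graph(8, "random", list(n_edges = 20), seed = 1)
  a <- simulate_roi_timeseries(g, fs = 125, duration = 5, seed = 7)
  b <- simulate_roi_timeseries(g, fs = 125, duration = 5, seed = 7)
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data), c(8L, 625L))
  expect_true(all(is.finite(a$data)))
  # microvolt scale: RMS near the requested amplitude
  expect_gt(mean(sqrt(rowMeans(a$data^2))), 10)
  expect_lt(mean(sqrt(rowMeans(a$data^2))), 40)
  expect_error(simulate_roi_timeseries(g, fs = -1, duration = 5), "positive")
})

test_that("fully coupled noiseless pairs are spectrally identical", {
  g <- dyad_graph(4)
  ts <- simulate_roi_timeseries(g, fs = 125, duration = 4.096,
                                coupling_gain = 1, noise_sd = 0, seed = 11)
  # planted effective distributions coincide within each dyad
  bp <- attr(ts, "band_profile")
  for (k in 1:4) expect_equal(bp[2 * k - 1, ], bp[2 * k, ], tolerance = 1e-12)
  # downstream RWE between the pair is ~0, far below unconnected pairs
  p <- band_energy_matrix(epoch_signals(ts, 256)$epochs[1, , ], fs = 125)
  m <- rwe_matrix(p)
  # planted distributions are exactly measurable (perfect-reconstruction
  # synthesis), so within-pair RWE vanishes to numerical precision
  connected <- vapply(1:4, function(k) m[2 * k - 1, 2 * k], numeric(1))
  unconnected <- m[1, 3]
  expect_lt(max(connected), 1e-8)
  expect_gt(unconnected, 0.01)
})

test_that("coupling pulls connected pairs together monotonically", {
  n_pairs <- 30L
  g <- dyad_graph(n_pairs)
  mean_rwe <- function(gain, seed) {
    ts <- simulate_roi_timeseries(g, fs = 125, duration = 4.096,
                                  coupling_gain = gain, seed = seed)
    m <- rwe_matrix(band_energy_matrix(epoch_signals(ts, 256)$epochs[1, , ],
                                       fs = 125))
    con <- vapply(seq_len(n_pairs), function(k) {
      (m[2 * k - 1, 2 * k] + m[2 * k, 2 * k - 1]) / 2
    }, numeric(1))
    mean(con)
  }
  gains <- c(0.2, 0.5, 0.9)
  # average over a few seeds at >= 50 pairs per gain level
  avg <- vapply(gains, function(gn) {
    mean(vapply(1:2, function(s) mean_rwe(gn, 100 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(avg) < 0))
})

test_that("zero coupling leaves connected pairs indistinguishable", {
  n_pairs <- 60L
  g <- dyad_graph(n_pairs)
  ts <- simulate_roi_timeseries(g, fs = 125, duration = 4.096,
                                coupling_gain = 0, seed = 13)
  m <- rwe_matrix(band_energy_matrix(epoch_signals(ts, 256)$epochs[1, , ],
                                     fs = 125))
  con <- vapply(seq_len(n_pairs), function(k) m[2 * k - 1, 2 * k], numeric(1))
  off <- vapply(seq_len(n_pairs - 1), function(k) m[2 * k - 1, 2 * k + 2],
                numeric(1))
  ht <- stats::t.test(con, off)
  expect_gt(ht$p.value, 0.01)
})

test_that("realized band energies recover the planted distributions", {
  # band waveforms are synthesised in the dual basis of the analysis
  # wavelet, so the spectral stage recovers the planted distributions
  # exactly up to floating point
  g <- generate_coupling_graph(16, "random", list(n_edges = 40), seed = 3)
  base <- rbind(
    matrix(rep(c(0.2, 0.2, 0.2, 0.2, 0.2), 4), 4, byrow = TRUE),
    matrix(rep(c(0.4, 0.3, 0.15, 0.1, 0.05), 4), 4, byrow = TRUE),
    matrix(rep(c(0.1, 0.1, 0.5, 0.2, 0.1), 4), 4, byrow = TRUE),
    matrix(rep(c(0.05, 0.1, 0.15, 0.3, 0.4), 4), 4, byrow = TRUE)
  )
  ts <- simulate_roi_timeseries(g, fs = 125, duration = 41,
                                band_profile = base, coupling_gain = 0,
                                noise_sd = 0, seed = 17)
  eps <- epoch_signals(ts, 256)
  p_hat <- Reduce(`+`, lapply(kept_epochs(eps), band_energy_matrix,
                              fs = 125)) /
    sum(eps$kept_mask)
  expect_lt(max(abs(p_hat - base)), 0.05)
  expect_lt(max(abs(p_hat - base)), 1e-9)
})

test_that("cohorts are reproducible with independent, effect-aware cells", {
  des <- cohort_design(n_per_group = 2, seed = 5,
                       effect_spec = list(dance_post = list(coupling_gain = 0.9)))
  expect_true(all(table(des$participants$group) == 2))
  co <- simulate_cohort(des, n_nodes = 16, fs = 125, duration = 4.096)
  co2 <- simulate_cohort(des, n_nodes = 16, fs = 125, duration = 4.096)
  expect_identical(co$cells[["p001.post"]]$ts$data,
                   co2$cells[["p001.post"]]$ts$data)
  expect_equal(length(co$cells), 8L)
  # every participant appears at both times
  expect_setequal(names(co$cells),
                  as.vector(outer(des$participants$id, c("pre", "post"),
                                  paste, sep = ".")))
  # the planted cell carries the modified parameter, others the baseline
  expect_equal(co$cells[["p001.post"]]$params$coupling_gain, 0.9)
  expect_equal(co$cells[["p001.pre"]]$params$coupling_gain, 0.35)
  expect_equal(co$cells[["p003.post"]]$params$coupling_gain, 0.35)
  # pre/post cells differ (independent state noise)
  expect_false(identical(co$cells[["p001.pre"]]$ts$data,
                         co$cells[["p001.post"]]$ts$data))

  expect_error(cohort_design(effect_spec = list(dance_banana = list(k = 1))),
               "unknown cells")
  expect_error(
    simulate_cohort(cohort_design(n_per_group = 1, seed = 1,
                                  effect_spec = list(dance_post = list(banana = 2))),
                    n_nodes = 8, fs = 125, duration = 4.096),
    "unknown parameters")
})
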