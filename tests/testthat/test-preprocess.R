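test_that("common-average reference zeroes the cross-channel mean", {
  x <- roi_timeseries(rbind(rep(10, 50), rep(0, 50)), fs = 500)
  r <- rereference_common_average(x)
  expect_equal(r$data[1, ], rep(5, 50))
  expect_equal(r$data[2, ], rep(-5, 50))

  # already zero-mean input is unchanged
  x2 <- roi_timeseries(rbind(rep(5, 50), rep(-5, 50)), fs = 500)
  expect_equal(rereference_common_average(x2)$data, x2$data)

  set.seed(11)
  x3 <- roi_timeseries(matrix(rnorm(57 * 1000), 57), fs = 500)
  r3 <- rereference_common_average(x3)
  expect_lt(max(abs(colMeans(r3$data))), 1e-9)

  expect_error(rereference_common_average(roi_timeseries(matrix(1, 1, 10), 500)),
               ">= 2 channels")
})

test_that("filter bank removes DC, notches 50 Hz, passes 10 Hz", {
  fs <- 500
  t <- seq_len(4000)
  x <- roi_timeseries(rbind(rep(7, 4000),
                            sin(2 * pi * 50 * t / fs),
                            sin(2 * pi * 10 * t / fs)), fs)
  f <- apply_filter_bank(x, quiet = TRUE)
  mid <- 1000:3000
  expect_lt(max(abs(f$data[1, mid])), 1e-9)
  atten_db <- 20 * log10(sd(f$data[2, mid]) / sd(x$data[2, mid]))
  expect_lt(atten_db, -20)
  ratio10 <- sd(f$data[3, mid]) / sd(x$data[3, mid])
  expect_lt(abs(ratio10 - 1), 0.05)
})

test_that("infeasible filter stages are skipped with a notice", {
  x <- roi_timeseries(matrix(rnorm(2 * 1000), 2), fs = 125)
  expect_message(apply_filter_bank(x), "beyond Nyquist")
  expect_error(apply_filter_bank(roi_timeseries(matrix(rnorm(20), 2), fs = 2)),
               "too low")
})

test_that("filtering is stable on long white noise and commutes with CAR", {
  set.seed(3)
  x <- roi_timeseries(matrix(rnorm(1e6), 1), fs = 500)
  # single-channel: skip CAR, filter directly
  f <- apply_filter_bank(x, quiet = TRUE)
  expect_true(all(is.finite(f$data)))

  set.seed(4)
  y <- roi_timeseries(matrix(rnorm(8 * 2000), 8), fs = 500)
  a <- apply_filter_bank(rereference_common_average(y), quiet = TRUE)
  b <- rereference_common_average(apply_filter_bank(y, quiet = TRUE))
  expect_lt(max(abs(a$data - b$data)) / max(abs(a$data)), 1e-6)
})

test_that("epoching yields floor(n/epoch_len) non-overlapping epochs", {
  x <- roi_timeseries(matrix(rnorm(2 * 150000), 2), fs = 500)
  e <- epoch_signals(x, 1024)
  expect_equal(dim(e$epochs)[1], 146)
  expect_equal(epoch_duration(e), 2.048)
  # first epoch is the first 1024 samples verbatim
  expect_equal(e$epochs[1, , ], unname(x$data[, 1:1024]))
  expect_equal(e$epochs[2, , ], unname(x$data[, 1025:2048]))

  e1 <- epoch_signals(roi_timeseries(matrix(rnorm(2 * 1024), 2), 500), 1024)
  expect_equal(dim(e1$epochs)[1], 1)
  expect_error(epoch_signals(roi_timeseries(matrix(rnorm(2 * 1023), 2), 500),
                             1024),
               "shorter than one epoch")
})

test_that("epoch rejection flags exactly the contaminated epochs", {
  gr <- dyad_graph(4)
  ts <- simulate_roi_timeseries(gr, fs = 125, duration = 12.3,
                                coupling_gain = 0.5, seed = 9)
  # clean signal, generous limit: everything kept
  e <- reject_epochs(epoch_signals(ts, 256), peak_to_peak_limit = 1e6)
  expect_true(all(e$kept_mask))

  # spike 10x the typical amplitude inside epoch 3
  spiked <- inject_spikes(ts, at = 2 * 256 + 100, amplitude = 10 * 20 * 4)
  e2 <- epoch_signals(spiked, 256)
  base_p2p <- max(apply(e2$epochs[1, , ], 1, function(r) diff(range(r))))
  e2 <- reject_epochs(e2, peak_to_peak_limit = base_p2p * 2)
  expect_false(e2$kept_mask[3])
  expect_true(all(e2$kept_mask[-3]))

  # kept + rejected = total
  expect_equal(sum(e2$kept_mask) + sum(!e2$kept_mask), length(e2$kept_mask))

  # infinite limit is the identity
  e3 <- reject_epochs(epoch_signals(spiked, 256), peak_to_peak_limit = Inf)
  expect_true(all(e3$kept_mask))

  expect_error(reject_epochs(epoch_signals(spiked, 256),
                             peak_to_peak_limit = 1e-12),
               "exceed")
})
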