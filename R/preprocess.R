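# Preprocessing: re-referencing, filter bank, epoching, epoch rejection.

#' Re-reference signals to the common average
#'
#' Subtracts, at every sample, the mean across all channels, so that the
#' cross-channel mean is exactly zero everywhere.
#'
#' @param x a \code{roi_ts} with at least two channels.
#' @return the re-referenced \code{roi_ts}.
#' @export
rereference_common_average <- function(x) {
  stopifnot(inherits(x, "roi_ts"))
  assert_that(n_rois(x) >= 2, "common-average reference needs >= 2 channels")
  x$data <- sweep(x$data, 2, colMeans(x$data), "-")
  x
}

#' The default EEG filter bank
#'
#' Five 3rd-order Butterworth stages applied in order: 1 Hz high-pass,
#' 47--53 Hz band-stop, 100 Hz low-pass, 97--103 Hz band-stop and
#' 147--153 Hz band-stop. Stages whose band reaches the Nyquist frequency of
#' the recording are skipped with a notice.
#'
#' @return a list of stage descriptors (type, cutoff frequencies in Hz).
#' @export
default_filter_bank <- function() {
  list(
    list(type = "high", w = 1),
    list(type = "stop", w = c(47, 53)),
    list(type = "low",  w = 100),
    list(type = "stop", w = c(97, 103)),
    list(type = "stop", w = c(147, 153))
  )
}

butter_stage <- function(stage, fs) {
  signal::butter(3, stage$w / (fs / 2), type = stage$type)
}

stage_feasible <- function(stage, fs) max(stage$w) < fs / 2

# Squared magnitude response |H(e^{i w})|^2 of an IIR filter on a frequency
# grid (w in radians/sample). The square is the zero-phase (forward-backward)
# effective response of the stage.
iir_mag2 <- function(flt, w) {
  z <- exp(-1i * outer(w, 0:(max(length(flt$b), length(flt$a)) - 1L)))
  num <- as.vector(z[, seq_along(flt$b), drop = FALSE] %*% flt$b)
  den <- as.vector(z[, seq_along(flt$a), drop = FALSE] %*% flt$a)
  Mod(num / den)^2
}

# Zero-phase filtering of a samples x channels matrix: the combined squared
# Butterworth magnitude response of all feasible stages is applied in the
# frequency domain after odd-reflection edge padding. Steady-state behaviour
# is identical to forward-backward time-domain application; only the edge
# transients differ.
zero_phase_filter_bank <- function(x, stages, fs) {
  n <- nrow(x)
  pad <- min(1000L, n - 1L)
  top <- 2 * x[rep(1L, pad), , drop = FALSE] - x[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * x[rep(n, pad), , drop = FALSE] -
    x[(n - 1L):(n - pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  # zero-pad to a highly composite FFT length; the discontinuity stays at
  # least `pad` samples away from the data
  target <- stats::nextn(nrow(xp), c(2L, 3L, 5L))
  if (target > nrow(xp)) {
    xp <- rbind(xp, matrix(0, target - nrow(xp), ncol(xp)))
  }
  np <- nrow(xp)
  w <- 2 * pi * (seq_len(np) - 1L) / np
  h2 <- rep(1, np)
  for (stage in stages) h2 <- h2 * iir_mag2(butter_stage(stage, fs), w)
  y <- Re(stats::mvfft(stats::mvfft(xp) * h2, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n), , drop = FALSE]
}

#' Apply the Butterworth filter bank
#'
#' Filters every channel through the stages of \code{bank}, in order, using
#' zero-phase forward-backward application so that epoch boundaries are not
#' shifted by group delay. Stages infeasible at the recording's sampling rate
#' (band edge at or above Nyquist) are skipped with a message.
#'
#' @param x a \code{roi_ts}; \code{x$fs} must exceed 2 Hz.
#' @param bank list of filter stages, see \code{\link{default_filter_bank}}.
#' @param quiet suppress the skipped-stage notices.
#' @return the filtered \code{roi_ts}.
#' @export
apply_filter_bank <- function(x, bank = default_filter_bank(), quiet = FALSE) {
  stopifnot(inherits(x, "roi_ts"))
  assert_that(x$fs > 2, "sampling rate %g Hz too low for the 1 Hz high-pass",
              x$fs)
  feasible <- list()
  for (stage in bank) {
    if (!stage_feasible(stage, x$fs)) {
      if (!quiet) {
        message(sprintf("skipping %s filter at [%s] Hz: beyond Nyquist (%g Hz)",
                        stage$type, paste(stage$w, collapse = "-"), x$fs / 2))
      }
      next
    }
    feasible[[length(feasible) + 1L]] <- stage
  }
  if (length(feasible) > 0) {
    x$data <- t(zero_phase_filter_bank(t(x$data), feasible, x$fs))
  }
  rownames(x$data) <- x$labels
  x
}

#' Split a recording into fixed-length non-overlapping epochs
#'
#' Consecutive windows of \code{epoch_len} samples; the trailing remainder is
#' discarded. 1,024 samples at 500 Hz gives the 2.048 s epochs the pipeline
#' is built around.
#'
#' @param x a \code{roi_ts}.
#' @param epoch_len epoch length in samples (default 1024).
#' @return an \code{epoch_set}: array \code{[n_epochs, n_rois, epoch_len]},
#'   sampling rate, epoch length and a per-epoch keep mask.
#' @export
epoch_signals <- function(x, epoch_len = 1024L) {
  stopifnot(inherits(x, "roi_ts"))
  epoch_len <- as.integer(epoch_len)
  assert_that(epoch_len >= 1, "epoch_len must be positive")
  ns <- n_samples(x)
  n_ep <- ns %/% epoch_len
  assert_that(n_ep >= 1,
              "recording of %d samples is shorter than one epoch (%d samples)",
              ns, epoch_len)
  nr <- n_rois(x)
  ep <- array(NA_real_, dim = c(n_ep, nr, epoch_len))
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- x$data[, ((e - 1L) * epoch_len + 1L):(e * epoch_len)]
  }
  structure(list(epochs = ep, fs = x$fs, epoch_len = epoch_len,
                 labels = x$labels, kept_mask = rep(TRUE, n_ep)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d kept) x %d ROIs x %d samples @ %g Hz (%.3f s/epoch)\n",
              dim(x$epochs)[1], sum(x$kept_mask), dim(x$epochs)[2],
              x$epoch_len, x$fs, epoch_duration(x)))
  invisible(x)
}

#' Epoch duration in seconds
#'
#' @param x an \code{epoch_set}.
#' @return \code{epoch_len / fs} in seconds.
#' @export
epoch_duration <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  x$epoch_len / x$fs
}

#' Reject epochs by peak-to-peak amplitude
#'
#' Marks as rejected every epoch whose peak-to-peak amplitude on any ROI
#' exceeds \code{peak_to_peak_limit}; an automated surrogate for visual
#' artifact screening. Original epoch indices are preserved in the mask.
#'
#' @param e an \code{epoch_set}.
#' @param peak_to_peak_limit positive amplitude limit in signal units
#'   (default 200, a conventional microvolt-scale artifact bound).
#' @return the \code{epoch_set} with an updated \code{kept_mask}. Errors if
#'   every epoch would be rejected.
#' @export
reject_epochs <- function(e, peak_to_peak_limit = 200) {
  stopifnot(inherits(e, "epoch_set"))
  assert_that(peak_to_peak_limit > 0, "peak-to-peak limit must be positive")
  n_ep <- dim(e$epochs)[1]
  nr <- dim(e$epochs)[2]
  p2p <- vapply(seq_len(n_ep), function(i) {
    m <- matrix(e$epochs[i, , ], nrow = nr)
    hi <- m[cbind(seq_len(nr), max.col(m, ties.method = "first"))]
    lo <- -(-m)[cbind(seq_len(nr), max.col(-m, ties.method = "first"))]
    max(hi - lo)
  }, numeric(1))
  keep <- e$kept_mask & (p2p <= peak_to_peak_limit)
  assert_that(any(keep), "all %d epochs exceed the %g peak-to-peak limit",
              n_ep, peak_to_peak_limit)
  e$kept_mask <- keep
  e
}

#' Extract the kept epochs as a list of ROI x sample matrices
#'
#' @param e an \code{epoch_set}.
#' @return a list with one \code{n_rois x epoch_len} matrix per kept epoch.
#' @export
kept_epochs <- function(e) {
  stopifnot(inherits(e, "epoch_set"))
  idx <- which(e$kept_mask)
  lapply(idx, function(i) {
    m <- e$epochs[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    rownames(m) <- e$labels
    m
  })
}

#' Preprocess a recording end to end
#'
#' Common-average reference, Butterworth filter bank, fixed-length epoching
#' and peak-to-peak epoch rejection, in that order.
#'
#' @param x a \code{roi_ts}.
#' @param epoch_len epoch length in samples.
#' @param peak_to_peak_limit rejection threshold (signal units).
#' @param bank filter bank; see \code{\link{default_filter_bank}}.
#' @param quiet suppress skipped-stage notices.
#' @return an \code{epoch_set}.
#' @export
preprocess <- function(x, epoch_len = 1024L, peak_to_peak_limit = 200,
                       bank = default_filter_bank(), quiet = TRUE) {
  x <- rereference_common_average(x)
  x <- apply_filter_bank(x, bank, quiet = quiet)
  e <- epoch_signals(x, epoch_len)
  reject_epochs(e, peak_to_peak_limit)
}
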