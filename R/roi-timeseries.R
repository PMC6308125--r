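#' Multi-ROI time series container
#'
#' A labelled matrix of ROI (or channel) signals with sampling-rate metadata;
#' the raw input of the pipeline. Values are microvolt-scale arbitrary units.
#'
#' @param data numeric matrix, one row per ROI, one column per sample.
#' @param fs sampling rate in Hz (> 0).
#' @param labels optional character vector of ROI names (default "roi001"...).
#' @return an object of class \code{roi_ts}.
#' @export
roi_timeseries <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  assert_that(is.numeric(data) && all(is.finite(data)),
              "signal matrix must be numeric and finite")
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0,
              "fs must be a single positive number")
  n <- nrow(data)
  if (is.null(labels)) labels <- sprintf("roi%03d", seq_len(n))
  assert_that(length(labels) == n,
              "got %d labels for %d ROIs", length(labels), n)
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d ROIs x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

n_rois <- function(x) nrow(x$data)
n_samples <- function(x) ncol(x$data)

#' Inject rectangular amplitude spikes into a recording
#'
#' Adds a short high-amplitude artifact to selected ROIs/samples, used to
#' exercise the amplitude-based epoch rejection stage.
#'
#' @param x a \code{roi_ts}.
#' @param at sample indices at which a spike starts.
#' @param amplitude spike amplitude in signal units.
#' @param roi ROI index (or indices) receiving the spike.
#' @param width spike width in samples.
#' @return the modified \code{roi_ts}.
#' @export
inject_spikes <- function(x, at, amplitude, roi = 1L, width = 5L) {
  stopifnot(inherits(x, "roi_ts"))
  assert_that(all(at >= 1 & at <= n_samples(x)), "spike positions out of range")
  for (s in at) {
    idx <- s:min(s + width - 1L, n_samples(x))
    x$data[roi, idx] <- x$data[roi, idx] + amplitude
  }
  x
}
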