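# Spectral stage: five-band relative wavelet energies and relative wavelet
# entropy (RWE) per epoch.
#
# Band/level mapping. Epochs are brought to a 125 Hz decision rate (a
# 1,024-sample epoch at 500 Hz becomes 256 samples), then a 5-level dyadic
# analysis aligns the detail levels with the canonical rhythms:
#   d1 31.25-62.5 Hz -> gamma      d2 15.6-31.25 -> beta
#   d3 7.8-15.6     -> alpha       d4 3.9-7.8    -> theta
#   d5 1.95-3.9     -> delta       approximation (< 1.95 Hz) discarded.

DECISION_FS <- 125

RWE_FLOOR <- 1e-12

#' Decompose one epoch (or a matrix of epochs) into five dyadic bands
#'
#' Resamples the signal(s) from \code{fs} to the 125 Hz decision rate by
#' polyphase rational resampling, then applies the 5-level periodized DWT.
#'
#' @param x numeric vector (one ROI's epoch) or matrix (ROIs x samples).
#' @param fs sampling rate of \code{x} in Hz; must be an integer multiple of
#'   125 (500 Hz in the reference protocol; 125 Hz is passed through).
#' @param wavelet wavelet family (default "bior5.5").
#' @return a \code{wavelet_decomposition} with \code{fs_effective = 125}.
#' @export
wavelet_decompose <- function(x, fs, wavelet = "bior5.5") {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  assert_that(fs >= DECISION_FS && (fs %% DECISION_FS) == 0,
              "fs = %g Hz is not a multiple of the %d Hz decision rate",
              fs, DECISION_FS)
  q <- fs / DECISION_FS
  if (q > 1) {
    x <- t(apply(x, 1, function(row) signal::resample(row, 1, q)))
  }
  n <- ncol(x)
  assert_that(n >= 2^5, "epoch of %d samples after resampling is shorter than 2^5", n)
  d <- dwt_periodized(if (single) drop(x) else x, levels = 5L, wavelet = wavelet)
  d$fs_effective <- DECISION_FS
  d
}

#' Relative band energies of a wavelet decomposition
#'
#' Absolute band energy is the sum of squared coefficients of the level
#' (gamma = d1 ... delta = d5, approximation discarded); relative energies
#' are normalised to sum to one, after flooring at 1e-12 so that downstream
#' log-ratios are defined.
#'
#' @param d a \code{wavelet_decomposition} of a single signal.
#' @return a \code{band_energy_distribution}: list with \code{p} (named
#'   delta..gamma, sums to 1), \code{raw_energy} and \code{e_tot}. Errors on
#'   zero total energy (flat signal).
#' @export
band_energies <- function(d) {
  stopifnot(inherits(d, "wavelet_decomposition"))
  assert_that(is.null(dim(d$details[[1]])),
              "band_energies expects a single-signal decomposition; see band_energy_matrix")
  raw <- vapply(d$details, function(cf) sum(cf^2), numeric(1))
  raw <- rev(raw)                       # d5..d1 -> delta..gamma
  names(raw) <- band_names()
  e_tot <- sum(raw)
  assert_that(e_tot > 0, "zero total band energy (flat signal)")
  p <- pmax(raw / e_tot, RWE_FLOOR)
  p <- p / sum(p)
  structure(list(p = p, raw_energy = raw, e_tot = e_tot),
            class = "band_energy_distribution")
}

#' @export
print.band_energy_distribution <- function(x, ...) {
  cat("<band_energy_distribution>\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Relative band energies for every ROI of one epoch
#'
#' @param epoch numeric matrix, ROIs x samples.
#' @param fs sampling rate in Hz.
#' @param wavelet wavelet family.
#' @return matrix (ROIs x 5) of relative band energies, rows summing to 1.
#' @export
band_energy_matrix <- function(epoch, fs, wavelet = "bior5.5") {
  d <- wavelet_decompose(epoch, fs, wavelet)
  raw <- vapply(d$details, function(cf) rowSums(cf^2), numeric(nrow(epoch)))
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  raw <- raw[, rev(seq_len(ncol(raw))), drop = FALSE]   # delta..gamma
  colnames(raw) <- band_names()
  rownames(raw) <- rownames(epoch)
  tot <- rowSums(raw)
  assert_that(all(tot > 0), "ROI(s) with zero total band energy: %s",
              paste(which(tot <= 0), collapse = ", "))
  p <- pmax(raw / tot, RWE_FLOOR)
  p / rowSums(p)
}

as_band_p <- function(x) {
  if (inherits(x, "band_energy_distribution")) x <- x$p
  x <- as.numeric(x)
  assert_that(length(x) == 5 && all(is.finite(x)) && all(x >= 0),
              "a band distribution is 5 finite nonnegative values")
  assert_that(sum(x) > 0, "band distribution sums to zero")
  x <- pmax(x / sum(x), RWE_FLOOR)
  x / sum(x)
}

#' Relative wavelet entropy between two band-energy distributions
#'
#' The Kullback-Leibler style divergence
#' \deqn{RWE(p, q) = \sum_{j=1}^{5} p_j \ln(p_j / q_j),}
#' zero iff the distributions coincide, asymmetric in its arguments, and
#' nonnegative by Gibbs' inequality. Inputs are floored at 1e-12 and
#' renormalised so the logarithm is always defined.
#'
#' @param p,q \code{band_energy_distribution} objects or numeric 5-vectors.
#' @return a nonnegative scalar.
#' @export
rwe <- function(p, q) {
  p <- as_band_p(p)
  q <- as_band_p(q)
  sum(p * log(p / q))
}

#' Pairwise RWE dissimilarity matrix for one epoch
#'
#' \code{values[i, j] = rwe(p_i, p_j)} (row ROI's distribution as the first
#' argument); the diagonal is exactly zero and discarded from analysis. The
#' matrix is generally asymmetric.
#'
#' @param p matrix (ROIs x 5) of relative band energies, or a list of
#'   \code{band_energy_distribution}s.
#' @param labels optional ROI labels.
#' @param epoch_index optional epoch number stored as an attribute.
#' @return an \code{rwe_matrix}: numeric n x n matrix with class attributes.
#' @export
rwe_matrix <- function(p, labels = NULL, epoch_index = NA_integer_) {
  if (is.list(p) && !is.data.frame(p)) {
    p <- do.call(rbind, lapply(p, as_band_p))
  }
  p <- as.matrix(p)
  assert_that(nrow(p) >= 2, "need at least 2 ROIs")
  assert_that(ncol(p) == 5, "expected 5 band columns, got %d", ncol(p))
  assert_that(all(is.finite(p)) && all(p >= 0), "invalid band energies")
  assert_that(all(rowSums(p) > 0), "ROI with zero total energy")
  p <- pmax(p / rowSums(p), RWE_FLOOR)
  p <- p / rowSums(p)
  lp <- log(p)
  self <- rowSums(p * lp)
  m <- self - p %*% t(lp)            # m[i,j] = sum_b p_ib (log p_ib - log p_jb)
  diag(m) <- 0
  m[m < 0] <- 0                      # clip numerical negatives ~ -1e-16
  if (is.null(labels)) labels <- rownames(p) %||% sprintf("roi%03d", seq_len(nrow(p)))
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("rwe_matrix", "matrix"),
            epoch_index = epoch_index)
}

#' @export
print.rwe_matrix <- function(x, ...) {
  cat(sprintf("<rwe_matrix> %d x %d, epoch %s, mean off-diagonal %.4f\n",
              nrow(x), ncol(x), attr(x, "epoch_index"),
              mean(x[row(x) != col(x)])))
  invisible(x)
}

#' Per-epoch RWE matrices for a preprocessed recording
#'
#' Computes the five-band energy distribution of every ROI in every kept
#' epoch and the corresponding RWE dissimilarity matrices.
#'
#' @param e an \code{epoch_set}.
#' @param wavelet wavelet family.
#' @return a list of \code{rwe_matrix}, one per kept epoch.
#' @export
epoch_rwe_matrices <- function(e, wavelet = "bior5.5") {
  stopifnot(inherits(e, "epoch_set"))
  eps <- kept_epochs(e)
  kept_idx <- which(e$kept_mask)
  nr <- dim(e$epochs)[2]
  # decompose all epochs in one stacked call (bounded block size), then
  # split the energy rows back into per-epoch matrices
  block <- max(1L, 16384L %/% max(nr, 1L))
  out <- vector("list", length(eps))
  i <- 1L
  while (i <= length(eps)) {
    j <- min(i + block - 1L, length(eps))
    big <- do.call(rbind, eps[i:j])
    p <- band_energy_matrix(big, e$fs, wavelet)
    for (k in i:j) {
      rows <- ((k - i) * nr + 1L):((k - i + 1L) * nr)
      out[[k]] <- rwe_matrix(p[rows, , drop = FALSE], labels = e$labels,
                             epoch_index = kept_idx[k])
    }
    i <- j + 1L
  }
  out
}
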