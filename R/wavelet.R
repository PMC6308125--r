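# Periodized discrete wavelet transform.
#
# No wavelet package ships with this environment, and the 5-level periodized
# DWT with a biorthogonal analysis pair is the core primitive of the method,
# so it is implemented here directly. Decomposition filters are fixed
# numerical constants of the named wavelet families.

.wavelet_filter_table <- list(
  # biorthogonal 5.5: 12-tap analysis pair
  bior5.5 = list(
    dec_lo = c(0, 0, 0.039687088347405436, 0.0079481086372403219,
               -0.054463788468236907, 0.34560528195603346,
               0.73666018142821055, 0.34560528195603346,
               -0.054463788468236907, 0.0079481086372403219,
               0.039687088347405436, 0),
    dec_hi = c(-0.013456709459118716, -0.0026949668801115071,
               0.13670658466432914, -0.093504697399938863,
               -0.47680326579848425, 0.89950610974864842,
               -0.47680326579848425, -0.093504697399938863,
               0.13670658466432914, -0.0026949668801115071,
               -0.013456709459118716, 0)
  ),
  # reverse biorthogonal 5.5 (analysis/synthesis sides swapped)
  rbio5.5 = list(
    dec_lo = c(0, 0.013456709459118716, -0.0026949668801115071,
               -0.13670658466432914, -0.093504697399938863,
               0.47680326579848425, 0.89950610974864842,
               0.47680326579848425, -0.093504697399938863,
               -0.13670658466432914, -0.0026949668801115071,
               0.013456709459118716),
    dec_hi = c(0, 0.039687088347405436, -0.0079481086372403219,
               -0.054463788468236907, -0.34560528195603346,
               0.73666018142821055, -0.34560528195603346,
               -0.054463788468236907, -0.0079481086372403219,
               0.039687088347405436, 0, 0)
  ),
  # symlet 8 (orthogonal, 16 taps): near-symmetric, energy-preserving
  sym8 = list(
    dec_lo = c(-3.3824159510061256e-03, -5.4213233179114812e-04,
               3.1695087811492981e-02, 7.6074873249176054e-03,
               -1.4329423835080971e-01, -6.1273359067658524e-02,
               4.8135965125837221e-01, 7.7718575170052351e-01,
               3.6444189483533140e-01, -5.1945838107709037e-02,
               -2.7219029917056003e-02, 4.9137179673607506e-02,
               3.8087520138906151e-03, -1.4952258337048231e-02,
               -3.0292051472136680e-04, 1.8899503327594609e-03),
    dec_hi = c(-1.8899503327594609e-03, -3.0292051472136680e-04,
               1.4952258337048231e-02, 3.8087520138906151e-03,
               -4.9137179673607506e-02, -2.7219029917056003e-02,
               5.1945838107709037e-02, 3.6444189483533140e-01,
               -7.7718575170052351e-01, 4.8135965125837221e-01,
               6.1273359067658524e-02, -1.4329423835080971e-01,
               -7.6074873249176054e-03, 3.1695087811492981e-02,
               5.4213233179114812e-04, -3.3824159510061256e-03)
  ),
  # daubechies 8 (orthogonal, 16 taps)
  db8 = list(
    dec_lo = c(-1.1747678412476953e-04, 6.7544940645056933e-04,
               -3.9174037337694705e-04, -4.8703529934515741e-03,
               8.7460940474057766e-03, 1.3981027917398282e-02,
               -4.4088253930794755e-02, -1.7369301001807547e-02,
               1.2874742662047847e-01, 4.7248457391328279e-04,
               -2.8401554296154691e-01, -1.5829105256349306e-02,
               5.8535468365420673e-01, 6.7563073629728976e-01,
               3.1287159091429995e-01, 5.4415842243104008e-02),
    dec_hi = c(-5.4415842243104008e-02, 3.1287159091429995e-01,
               -6.7563073629728976e-01, 5.8535468365420673e-01,
               1.5829105256349306e-02, -2.8401554296154691e-01,
               -4.7248457391328279e-04, 1.2874742662047847e-01,
               1.7369301001807547e-02, -4.4088253930794755e-02,
               -1.3981027917398282e-02, 8.7460940474057766e-03,
               4.8703529934515741e-03, -3.9174037337694705e-04,
               -6.7544940645056933e-04, -1.1747678412476953e-04)
  )
)

#' Decomposition filters of a supported wavelet family
#'
#' @param wavelet one of "bior5.5" (default analysis family), "rbio5.5",
#'   "sym8", "db8".
#' @return list with numeric vectors \code{dec_lo} and \code{dec_hi}.
#' @export
wavelet_filters <- function(wavelet = "bior5.5") {
  f <- .wavelet_filter_table[[wavelet]]
  if (is.null(f)) {
    stopf("unknown wavelet '%s' (supported: %s)", wavelet,
          paste(names(.wavelet_filter_table), collapse = ", "))
  }
  f
}

# One analysis step under periodization: circular convolution with the
# decomposition filter followed by dyadic downsampling. x may be a matrix
# (one signal per row); the step is applied to every row at once.
dwt_step <- function(x, filt) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  half <- n %/% 2L
  out <- matrix(0, nrow(x), half)
  pos <- 2L * seq_len(half) - 1L          # odd output phase (1-based)
  for (k in seq_along(filt)) {
    if (filt[k] == 0) next
    idx <- (pos - (k - 1L) - 1L) %% n + 1L  # circular x[(t - k) mod n]
    out <- out + filt[k] * x[, idx, drop = FALSE]
  }
  out
}

#' Periodized multilevel discrete wavelet transform
#'
#' A non-redundant dyadic analysis: at each level the running approximation
#' is circularly convolved with the decomposition low/high-pass pair and
#' downsampled by two, so the total coefficient count equals the input
#' length. Accepts a matrix to decompose many signals at once.
#'
#' @param x numeric vector, or matrix with one signal per row. The length
#'   must be divisible by \code{2^levels} and leave at least one coefficient
#'   at the coarsest level.
#' @param levels number of decomposition levels (default 5).
#' @param wavelet wavelet family name, see \code{\link{wavelet_filters}}.
#' @return a \code{wavelet_decomposition}: list with \code{details} (list
#'   d1..d\code{levels}, finest first; matrices if the input was a matrix),
#'   \code{approx}, \code{wavelet}, \code{levels}, \code{n}.
#' @export
dwt_periodized <- function(x, levels = 5L, wavelet = "bior5.5") {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  assert_that(n %% (2^levels) == 0 && n >= 2^levels,
              "signal length %d not divisible by 2^%d", n, levels)
  f <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  approx <- x
  for (j in seq_len(levels)) {
    details[[j]] <- dwt_step(approx, f$dec_hi)
    approx <- dwt_step(approx, f$dec_lo)
  }
  names(details) <- paste0("d", seq_len(levels))
  if (single) {
    details <- lapply(details, drop)
    approx <- drop(approx)
  }
  structure(list(details = details, approx = approx, wavelet = wavelet,
                 levels = levels, n = n),
            class = "wavelet_decomposition")
}

# Adjoint of dwt_step: scatter coefficient rows back to signal positions.
# For orthogonal families the adjoint of the analysis operator is its
# inverse, so composing adjoint steps reconstructs the signal exactly.
idwt_step <- function(coef, filt) {
  if (is.null(dim(coef))) coef <- matrix(coef, nrow = 1)
  half <- ncol(coef)
  n <- 2L * half
  out <- matrix(0, nrow(coef), n)
  pos <- 2L * seq_len(half) - 1L
  for (k in seq_along(filt)) {
    if (filt[k] == 0) next
    idx <- (pos - (k - 1L) - 1L) %% n + 1L
    out[, idx] <- out[, idx] + filt[k] * coef
  }
  out
}

# Dual family whose decomposition filters act as the synthesis filters of
# `wavelet` under the adjoint-step convention: orthogonal families are
# self-dual, the biorthogonal 5.5 pair are each other's duals.
dual_wavelet <- function(wavelet) {
  switch(wavelet, bior5.5 = "rbio5.5", rbio5.5 = "bior5.5", wavelet)
}

#' Inverse periodized multilevel DWT
#'
#' Reconstructs a signal from its periodized decomposition by composing
#' synthesis steps built from the dual family's filters: exact perfect
#' reconstruction for the orthogonal families ("sym8", "db8", self-dual) and
#' for the biorthogonal pair ("bior5.5"/"rbio5.5", dual to each other).
#'
#' @param details list of detail coefficient vectors/matrices, finest first.
#' @param approx coarsest approximation coefficients.
#' @param wavelet the analysis wavelet the decomposition came from.
#' @return the reconstructed signal (vector or matrix matching the input).
#' @export
idwt_periodized <- function(details, approx, wavelet = "sym8") {
  f <- wavelet_filters(dual_wavelet(wavelet))
  single <- is.null(dim(approx)) && is.null(dim(details[[1]]))
  x <- approx
  for (j in rev(seq_along(details))) {
    x <- idwt_step(x, f$dec_lo) + idwt_step(details[[j]], f$dec_hi)
  }
  if (single) x <- drop(x)
  x
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  len <- vapply(x$details, function(d) {
    if (is.null(dim(d))) length(d) else ncol(d)
  }, numeric(1))
  cat(sprintf("<wavelet_decomposition> %s, %d levels (detail lengths %s), n = %d\n",
              x$wavelet, x$levels, paste(len, collapse = "/"), x$n))
  invisible(x)
}
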