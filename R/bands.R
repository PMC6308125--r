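#' Canonical EEG frequency bands
#'
#' The five classical rhythms analysed by the pipeline, in Hz. Gamma is
#' capped at 45 Hz so that band content stays inside the analysed spectrum
#' (below the 47--53 Hz notch and the dyadic analysis ceiling at a 125 Hz
#' decision-stage rate).
#'
#' @return a named list of c(low, high) frequency edges in Hz.
#' @export
eeg_bands <- function() {
  list(
    delta = c(1, 4),
    theta = c(4, 8),
    alpha = c(8, 13),
    beta  = c(13, 30),
    gamma = c(30, 45)
  )
}

band_names <- function() c("delta", "theta", "alpha", "beta", "gamma")

# Oscillator frequencies for the synthetic generator. Each is an exact
# multiple of the 2.048 s epoch rate (125/256 Hz), so the oscillation is
# periodic over an epoch and the periodized wavelet analysis sees no
# wrap-around discontinuity; within each band, the multiples whose energy is
# best contained in the band's own wavelet level were kept (placements near
# the dyadic transition bands leak into neighbouring levels). All lie inside
# the canonical bands and below the 47--53 Hz notch.
osc_band_frequencies <- function() {
  bin <- 125 / 256
  list(
    delta = bin * c(5, 6),
    theta = bin * c(10, 11, 12),
    alpha = bin * c(21, 22, 23, 24),
    beta  = bin * c(42, 43, 44, 45, 46, 47),
    gamma = bin * c(84, 85, 86, 87, 88, 89)
  )
}
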