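# Synthetic ROI signal generator.
#
# Each node's signal is a weighted sum of five band-limited oscillations
# (delta..gamma) plus white noise. The weights are the square roots of the
# node's effective band-energy distribution, so relative band energies are
# the planted quantity — exactly what relative wavelet entropy compares.
#
# Coupling model: connected nodes are pulled toward a shared distribution by
# damped consensus diffusion on the (symmetrised) coupling graph. With base
# distributions X0 and row-normalised adjacency W, the effective
# distributions solve
#     X = (1 - g) X0 + g W X   =>   X = (1 - g) (I - g W)^{-1} X0,
# a convex (hence distribution-valued) combination. g = 0 leaves nodes
# independent; g = 1 collapses every weakly connected component to its
# consensus, so connected pairs become identical.
#
# The five band waveforms are shared across nodes within one recording
# (fixed frequency grid inside each band core, random phases); every node
# weights each band waveform with a random sign. RWE is phase-blind, so the
# shared waveforms carry no pairwise information beyond the planted energy
# distributions, while the random signs keep the cross-channel mean near
# zero under common-average referencing.

dirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

#' Canonical module spectral prototypes
#'
#' Fixed relative band-energy profiles (delta, theta, alpha, beta, gamma)
#' emulating the characteristic rhythms of cortical territories: a
#' slow-dominant frontal profile, a posterior alpha profile, a sensorimotor
#' beta profile and a mixed fast profile. Modules beyond the fourth recycle
#' the list.
#'
#' @param n_modules number of prototype rows to return.
#' @return matrix (n_modules x 5), rows summing to 1.
#' @export
module_prototypes <- function(n_modules = 4L) {
  base <- rbind(
    c(0.35, 0.35, 0.15, 0.10, 0.05),
    c(0.10, 0.10, 0.60, 0.15, 0.05),
    c(0.10, 0.10, 0.20, 0.50, 0.10),
    c(0.15, 0.15, 0.20, 0.20, 0.30)
  )
  out <- base[((seq_len(n_modules) - 1L) %% 4L) + 1L, , drop = FALSE]
  colnames(out) <- band_names()
  out
}

#' Draw per-node base band-energy distributions
#'
#' For modular graphs each node's base is a mixture of its module's
#' canonical prototype and an individual flat-Dirichlet draw; otherwise
#' nodes are i.i.d. flat-Dirichlet. Uses the current RNG state.
#'
#' @param n_nodes number of nodes.
#' @param modules optional 1-based module id per node.
#' @param prototype_mix weight of the module prototype (default 0.6).
#' @return matrix (n_nodes x 5), rows summing to 1.
#' @export
default_band_profile <- function(n_nodes, modules = NULL,
                                 prototype_mix = 0.6) {
  jitter <- dirichlet_rows(n_nodes, rep(1, 5))
  if (is.null(modules)) return(jitter)
  proto <- module_prototypes(max(modules))
  (1 - prototype_mix) * jitter +
    prototype_mix * proto[modules, , drop = FALSE]
}

# Balanced random signs per band: the cross-channel mean stays near zero so
# common-average referencing leaves the planted energy geometry intact.
balanced_signs <- function(n, n_bands = 5L) {
  half <- n %/% 2L
  base <- c(rep(-1, half), rep(1, n - half))
  vapply(seq_len(n_bands), function(b) sample(base), numeric(n))
}

#' Effective band-energy distributions under graph coupling
#'
#' @param graph a \code{bdgraph}.
#' @param base matrix (n x 5) of base distributions, rows summing to 1.
#' @param coupling_gain g in [0, 1].
#' @return matrix (n x 5) of effective distributions.
#' @export
couple_band_profiles <- function(graph, base, coupling_gain) {
  assert_that(coupling_gain >= 0 && coupling_gain <= 1,
              "coupling_gain must lie in [0, 1]")
  n <- graph$n_nodes
  assert_that(nrow(base) == n, "base profile must have one row per node")
  if (coupling_gain == 0) return(base)
  s <- (graph$adjacency + t(graph$adjacency)) > 0
  deg <- rowSums(s)
  if (coupling_gain >= 1) {
    # consensus within each weakly connected component
    comp <- igraph::components(as_igraph(graph), mode = "weak")$membership
    x <- base
    for (cm in unique(comp)) {
      idx <- which(comp == cm)
      x[idx, ] <- matrix(colMeans(base[idx, , drop = FALSE]),
                         length(idx), 5, byrow = TRUE)
    }
    return(x)
  }
  w <- s / pmax(deg, 1)
  iso <- which(deg == 0)
  if (length(iso) > 0) {
    w[iso, ] <- 0
    w[cbind(iso, iso)] <- 1   # isolated nodes keep their base distribution
  }
  x <- solve(diag(n) - coupling_gain * w, (1 - coupling_gain) * base)
  x / rowSums(x)
}

# One epoch of band-limited stochastic oscillation for band b (1 = delta ..
# 5 = gamma): random Gaussian coefficients in that band's detail level,
# reconstructed through the synthesis (dual) basis of the analysis wavelet
# and normalised to unit mean-square energy. By perfect reconstruction, the
# analysis stage sees exactly the planted coefficients, so the realized
# wavelet band energies of a weighted sum of such waveforms equal the
# squared weights exactly (no cross-band interference).
band_waveform_epochs <- function(band, n_ep, epoch_len, levels,
                                 wavelet = "bior5.5") {
  level <- levels - band + 1L         # delta = coarsest detail level
  len <- epoch_len %/% 2^level
  coef <- matrix(stats::rnorm(n_ep * len), n_ep, len)
  # fixed energy on the analysis side: measured relative band energies of a
  # weighted sum are then exactly the squared weights, for any wavelet;
  # the time-domain mean square is ~1 (exactly 1 for orthogonal wavelets)
  coef <- coef * sqrt(epoch_len) / sqrt(rowSums(coef^2))
  details <- lapply(seq_len(levels), function(j) {
    matrix(0, n_ep, epoch_len %/% 2^j)
  })
  details[[level]] <- coef
  idwt_periodized(details, matrix(0, n_ep, epoch_len %/% 2^levels), wavelet)
}

# Shared band waveforms for a whole recording, synthesised epoch by epoch on
# the 2.048 s grid so the periodized per-epoch analysis sees exactly the
# planted band energies.
shared_band_waveforms <- function(n_samples, fs, wavelet = "bior5.5") {
  assert_that(fs >= DECISION_FS && log2(fs / DECISION_FS) %% 1 == 0,
              "fs = %g Hz must be 125 * 2^k for the synthetic generator", fs)
  epoch_len <- as.integer(256 * fs / DECISION_FS)
  levels <- 5L + as.integer(log2(fs / DECISION_FS))
  n_ep <- as.integer(ceiling(n_samples / epoch_len))
  u <- matrix(0, 5, n_ep * epoch_len)
  for (b in 1:5) {
    w <- band_waveform_epochs(b, n_ep, epoch_len, levels, wavelet)
    u[b, ] <- as.vector(t(w))
  }
  u[, seq_len(n_samples), drop = FALSE]
}

#' Simulate ROI time series with planted band-energy coupling
#'
#' @param graph a \code{bdgraph} coupling topology (see
#'   \code{\link{generate_coupling_graph}}).
#' @param fs sampling rate in Hz (default 500).
#' @param duration recording length in seconds (default 300, i.e. ~5 min).
#' @param band_profile optional n x 5 matrix of per-node base relative band
#'   energies. Default: for modular graphs, module-specific spectral
#'   prototypes mixed with per-node jitter; otherwise i.i.d. flat-Dirichlet
#'   draws.
#' @param coupling_gain strength g in [0, 1] of the pull toward a shared
#'   distribution along graph edges (default 0.5).
#' @param noise_sd white-noise amplitude in signal units (default 1; signals
#'   have RMS \code{amplitude}).
#' @param seed integer seed; output is reproducible given the seed.
#' @param amplitude oscillation RMS in microvolt-scale units (default 20).
#' @param prototype_mix for modular defaults: weight of the module prototype
#'   in each node's base distribution (default 0.6).
#' @param wavelet analysis wavelet whose synthesis (dual) basis generates the
#'   band waveforms; keep equal to the spectral stage's wavelet so planted
#'   band energies are exactly measurable (default "bior5.5").
#' @return a \code{roi_ts} with attributes \code{band_profile} (effective
#'   distributions actually planted) and \code{graph}.
#' @export
simulate_roi_timeseries <- function(graph, fs = 500, duration = 300,
                                    band_profile = NULL, coupling_gain = 0.5,
                                    noise_sd = 1, seed = 1L, amplitude = 20,
                                    prototype_mix = 0.6, wavelet = "bior5.5") {
  stopifnot(inherits(graph, "bdgraph"))
  assert_that(fs > 0 && duration > 0, "fs and duration must be positive")
  n <- graph$n_nodes
  n_samples <- floor(fs * duration)
  assert_that(n_samples >= 1, "empty recording")
  with_seed(seed, {
    if (is.null(band_profile)) {
      band_profile <- default_band_profile(n, graph$modules, prototype_mix)
    }
    band_profile <- as.matrix(band_profile)
    assert_that(nrow(band_profile) == n && ncol(band_profile) == 5,
                "band_profile must be n_nodes x 5")
    band_profile <- band_profile / rowSums(band_profile)
    x_eff <- couple_band_profiles(graph, band_profile, coupling_gain)
    u <- shared_band_waveforms(n_samples, fs, wavelet)
    signs <- balanced_signs(n)
    data <- amplitude * ((signs * sqrt(x_eff)) %*% u)
    if (noise_sd > 0) {
      data <- data + noise_sd * matrix(stats::rnorm(n * n_samples), n,
                                       n_samples)
    }
    out <- roi_timeseries(data, fs)
    attr(out, "band_profile") <- x_eff
    attr(out, "graph") <- graph
    out
  })
}
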