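---
title: "Methods: relative wavelet entropy connectomes and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative wavelet entropy connectomes and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rweconn)
```

## The estimation problem

Resting-state EEG source activity, averaged within cortical regions of
interest (ROIs), carries a spectral fingerprint per region: the way its
power is distributed over the five classical rhythms (delta 1--4 Hz, theta
4--8, alpha 8--13, beta 13--30, gamma 30--45). Two regions whose
fingerprints agree are taken to be functionally synchronised. `rweconn`
builds directed functional brain networks from this idea and tests whether
an intervention (the motivating design contrasts a dance-training group with
an active control group, each measured before and after the programme)
changes the network's global organisation.

The pipeline is:

1. **Preprocessing.** Common-average re-referencing; a bank of 3rd-order
   Butterworth filters (1 Hz high-pass; band-stops at 47--53, 97--103 and
   147--153 Hz; 100 Hz low-pass), applied zero-phase; segmentation into
   non-overlapping 1,024-sample epochs (2.048 s at 500 Hz); rejection of any
   epoch whose peak-to-peak amplitude exceeds a configurable bound (default
   200 units) — an automated surrogate for visual artifact screening.
2. **Spectral stage.** Each epoch is brought to a 125 Hz decision rate
   (1,024 samples become 256) and decomposed by a 5-level periodized
   discrete wavelet transform with the biorthogonal 5.5 analysis pair.
   Detail levels align with the canonical rhythms (d1 31.25--62.5 Hz
   `=` gamma, d2 beta, d3 alpha, d4 theta, d5 delta; the final approximation
   below 1.95 Hz is discarded). Band energy is the sum of squared
   coefficients of the level; relative energies are floored at 1e-12 and
   normalised to sum to one.
3. **Connectivity.** For ROIs *i*, *j* with band-energy distributions *p*,
   *q*, the relative wavelet entropy
   \(\mathrm{RWE}(p, q) = \sum_{j=1}^{5} p_j \ln(p_j/q_j)\)
   is a nonnegative, asymmetric dissimilarity: zero only for identical
   spectra. Per epoch this yields an n x n matrix with zero diagonal.
4. **Network construction.** Each epoch's matrix is thresholded to a fixed
   edge count — 10,000, 12,500 and 15,000 edges for the 512-ROI protocol —
   by connecting the most-synchronised (smallest-RWE) ordered pairs, with
   deterministic (value, source, target) tie-breaking so nested edge counts
   give nested graphs.
5. **Graph metrics.** Directed clustering (Fagiolo's all-motif
   generalisation), characteristic path length over reachable ordered pairs
   (the unreachable fraction is reported), betweenness hubs
   (\(B_i \ge 1.5\), betweenness normalised by the network mean), community
   structure by modularity maximisation, within-module degree z-score,
   participation coefficient, and the seven-role functional cartography.
   The small-world index \(\sigma = (C/C_{rand})/(L/L_{rand})\) is computed
   against 100 random directed graphs with identical node and edge counts.
   Metrics are computed per epoch and averaged per recording.
6. **Inference.** A 2x2 mixed ANOVA (group between, time within) per metric
   and density; paired t-tests; Pearson correlations against behavioural
   scores; and a repeated-measures power analysis based on the noncentral F
   distribution with \(\lambda = f^2 N m \epsilon/(1-\rho)\) (the
   convention of the G*Power program), which for f = 0.21, alpha = 0.05 and
   target power 0.80 returns a minimal balanced N of 48.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `epoch_len` | 1,024 samples | epoch duration 2.048 s at 500 Hz |
| `peak_to_peak_limit` | 200 units | epoch artifact bound, microvolt scale |
| `densities` | 10,000 / 12,500 / 15,000 | fixed edge counts of the binary graphs |
| `n_nulls` | 100 | random graphs per null ensemble |
| `wavelet` | `"bior5.5"` | analysis family (also `rbio5.5`, `sym8`, `db8`) |
| hub thresholds | 1.5 / 1.5 | relative betweenness; within-module z |
| role boundaries | printed values | P cut-points 0.05/0.45/0.70 (non-hubs), 0.25/0.50 (hubs) |

## Numerical choices

* **Zero-phase filtering** is applied in the frequency domain: the squared
  magnitude response of the cascaded Butterworth stages multiplies the FFT
  of the (odd-reflection padded) signal. This equals forward–backward
  time-domain filtering in steady state and differs only in edge
  transients; it filters all channels in one pass. Stages whose band reaches
  the Nyquist frequency are skipped with a notice.
* **Band/level mapping.** A literal per-band coefficient count cannot be
  reconciled with 1,024-sample epochs and five levels, so epochs are
  resampled to 125 Hz where five dyadic levels align with the canonical
  rhythms (see above). The resampling is polyphase; recordings already at
  125 Hz pass through untouched.
* **RWE guards.** Relative energies are floored at 1e-12 and renormalised
  before the logarithm, so narrowband signals (zero energy in some band)
  cannot produce infinities. Direction convention: `values[i, j]` uses row
  *i*'s distribution as the first argument.
* **Thresholding direction.** RWE is a dissimilarity, so edges connect the
  *smallest* values; the opposite convention is available behind a flag for
  sensitivity analysis.
* **Unreachable pairs** are excluded from the characteristic path length
  (with their fraction reported) rather than set to infinity; a
  harmonic-mean variant is available behind a flag. At 10,000 edges
  (density ~3.8%) weak connectivity of a 512-node graph is not guaranteed,
  so this choice is load-bearing and documented in every output.
* **Directed conventions.** Clustering uses Fagiolo's all-motif formula
  (reduces to the classic coefficient on symmetric graphs); betweenness is
  exact directed Brandes; within-module degree and participation use total
  (in+out) degree, with in-only/out-only options. Community detection
  maximises modularity on the symmetrised graph (edge weight = number of
  directed edges between the pair) with a seeded Louvain run, because no
  directed-modularity Louvain is available in the graph library used; a
  fixed seed makes partitions reproducible.
* **Mixed ANOVA** is computed by the exact average/difference-score
  decomposition for the 2 (between) x 2 (within) design; it matches
  `aov(value ~ group*time + Error(participant/time))` to machine precision
  on balanced data and degrades gracefully on degenerate inputs (zero
  variance with zero effect returns F = 0, p = 1).

## The synthetic-data generator

Every downstream stage is validated against recordings with known ground
truth, produced by `generate_coupling_graph()` (random / ring-lattice /
Watts–Strogatz / modular planted-partition topologies),
`simulate_roi_timeseries()` and `simulate_cohort()`.

**Signal model.** Each node's signal is a weighted sum of five shared
band-limited stochastic oscillations plus white noise; the weights are the
square roots of the node's band-energy distribution, with balanced random
signs across nodes. The design is built around what the estimator can see:

* RWE is phase-blind — it compares band-energy distributions only — so
  coupling is modelled on the distributions, not on waveform phase.
* The five band waveforms are *shared* across nodes within a recording and
  synthesised per 2.048 s epoch in the wavelet domain: random coefficients
  in the band's own detail level, reconstructed through the synthesis
  (dual) basis of the analysis wavelet and normalised on the analysis side.
  By perfect reconstruction, the spectral stage recovers each node's
  planted distribution *exactly* (the band-realism test checks 1e-9), and
  spectral leakage is common to all nodes, cancelling from pairwise
  comparisons.
* The balanced signs keep the cross-channel mean near zero, so
  common-average referencing does not distort the planted energy geometry.

**Coupling.** With base distributions \(X_0\) and the row-normalised
symmetrised adjacency \(W\) of the ground-truth graph, effective
distributions solve \(X = (1-g)X_0 + gWX\) — damped consensus diffusion.
\(g = 0\) leaves nodes independent; \(g = 1\) collapses each weakly
connected component to its consensus, so connected pairs become identical
and their RWE vanishes. Expected within-pair RWE decreases monotonically in
\(g\) (property-tested over 60 dyads at three gain levels).

**Cohorts.** `cohort_design()` describes a two-group (dance / active)
pre/post design; `effect_spec` modifies generator parameters in named cells
(e.g. `dance_post`). Per-cell seeds are derived by hashing (master seed,
participant id, time), so cells are independent but the whole cohort is
reproducible. A participant's base spectral profile is treated as a stable
trait (derived from a participant-level seed and shared by the pre and post
recordings); graph realisation, waveform phases and noise are per-cell
state. For modular topologies, node bases mix an individual flat-Dirichlet
draw with fixed canonical module prototypes (slow-dominant frontal,
posterior alpha, sensorimotor beta, mixed fast profiles; default mix 0.6).

**What the planted intervention effect is — and why.** Thresholded RWE
networks are geometry: each node contributes one point in the 4-simplex of
band-energy distributions, and edges connect the closest ordered pairs.
Simulation shows (and the package's tests exploit) that such graphs cannot
encode an arbitrary planted edge set — rewiring a Watts–Strogatz truth
barely moves the estimated network, because long-range "shortcut" edges
have no geometric counterpart; the estimated small-world index of any
generic point cloud at fixed density hovers near 3. What *does* move the
estimated metrics is the organisation of the distribution cloud. The
default planted effect therefore raises the coupling gain of the dance-post
cell (0.35 baseline to 0.9) on a modular ground truth: stronger coupling
tightens the module clusters, the fixed edge budget concentrates inside
them, clustering rises and the characteristic path length over reachable
pairs drops — estimated sigma roughly doubles. This mirrors the motivating
finding (higher small-worldness driven by shorter path length after
training) and is detectable by the 2x2 interaction test in essentially
every simulated cohort at 22 participants per group. Coupling gain is a
first-class `effect_spec` field precisely because it is the generator's
honest lever on network organisation.

**Study-scale choices.** The validation cohorts use 64 ROIs, 20 epochs per
recording and signals generated natively at the 125 Hz decision rate with
256-sample epochs (the identical 2.048 s duration; the spectral stage is
bit-identical at this rate and only the above-Nyquist notch stages are
skipped). Parameter recovery uses 20 effect cohorts and 40 null cohorts of
22 participants per group; null ensembles use 30 random graphs there, which
only rescales all sigma values by a common factor and leaves the ANOVA
untouched. The full 512-ROI, 100-null configuration is exercised by the
small-world acceptance checks.

**What passing tests do and do not show.** The generator emulates
epoch-stationary, band-limited source activity with additive white noise
and optional amplitude spikes; it does not emulate volume conduction,
eye-blink or muscle artifacts, 1/f broadband structure, non-stationary
rhythms, or inter-epoch drift. Ground-truth recovery on these signals
demonstrates that the pipeline measures what it claims to measure, not that
real EEG satisfies the model; with real data, artifact cleaning (e.g. ICA)
is assumed to have happened upstream.

## Known limitations

* Biorthogonal analysis energies are not signal-subspace energies; with the
  default bior5.5 family the *absolute* band-energy estimates of generic
  (non-dual-synthesised) signals carry a systematic bias of up to ~0.1 in
  relative energy. Pairwise RWE comparisons are unaffected in so far as the
  distortion is common across channels; orthogonal families (`sym8`,
  `db8`) are available where unbiased energies matter.
* Thresholded RWE graphs are geometric: hub structure, cartography and
  small-world indices reflect the shape of the band-energy distribution
  cloud. Interpreting them as an anatomical wiring diagram over-reads the
  estimator (this limitation belongs to the method itself, not to this
  implementation).
* Weighted-network analysis is out of scope; graphs are binary at fixed
  edge counts.
* The mixed ANOVA reports uncorrected p-values across metrics and densities
  by default, matching the motivating analysis; Holm adjustment is left to
  the caller (`p.adjust`).
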