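# rweconn

Directed functional brain networks from multichannel resting-state EEG (or
cortical ROI time series), estimated with **relative wavelet entropy (RWE)**
between five-band wavelet energy distributions, thresholded to fixed edge
counts, and characterised with small-world, hub and functional-cartography
graph metrics — plus the group statistics of a two-group pre/post
intervention design and a synthetic-data generator with known ground truth
for validating every stage.

The package is written for researchers who study intervention-induced
neuroplasticity with EEG connectomics: the motivating design contrasts a
dance-training group with an active control group, recorded at rest before
and after a six-month programme, and asks whether the cortical network's
small-world organisation changes.

## The method in brief

Per epoch (1,024 samples, 2.048 s at 500 Hz) and per region, a 5-level
periodized discrete wavelet transform (biorthogonal 5.5 family) yields the
relative energies *p*<sub>j</sub> of the five rhythms (delta, theta, alpha,
beta, gamma), with total energy
E<sub>tot</sub> = Σ<sub>j</sub> Σ<sub>k</sub> |C<sub>j</sub>(k)|².
Synchronisation of regions *i*, *j* is the dissimilarity

> RWE(p, q) = Σ<sub>j=1..5</sub> p<sub>j</sub> ln(p<sub>j</sub>/q<sub>j</sub>) ≥ 0,

zero only for identical spectra. Thresholding each epoch's RWE matrix to a
fixed edge count (10,000 / 12,500 / 15,000 for 512 ROIs) gives binary
directed graphs, scored by:

* mean directed clustering C and characteristic path length L;
* the small-world index σ = (C/C<sub>rand</sub>) / (L/L<sub>rand</sub>)
  against 100 density-matched random digraphs;
* betweenness hubs (B<sub>i</sub> ≥ 1.5, mean-normalised betweenness);
* modularity communities, within-module z-score, participation coefficient
  and the seven Guimerà–Amaral node roles.

Group inference is a 2×2 mixed ANOVA (group × time) per metric and density,
with paired t-tests, Pearson correlations and a noncentral-F
repeated-measures power analysis (f = 0.21, α = 0.05, power 0.80 → N = 48).

See the methods vignette (`vignettes/rwe-connectome-methods.Rmd`) for the
model, numerical choices and the validation design.

## Worked example

Simulate and analyse a bundled 16-node demo cohort (2 participants per
group, one density, a planted coupling increase in the dance-post cell):

```r
library(rweconn)
cfg <- read_run_config(system.file("extdata", "demo_config.json",
                                   package = "rweconn"))
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result> 8 cells, 24 panel rows (config 00888b85)
#> time x group interactions:
#>  metric density_label         F df1 df2          p
#>  c_mean            40  2.008222   1   2 0.29216833
#>  l_mean            40 13.508202   1   2 0.06670691
#>   sigma            40  6.958623   1   2 0.11866499

aggregate(cbind(sigma, l_mean) ~ group + time, res$global,
          function(x) round(mean(x), 3))
#>    group time sigma l_mean
#> 1 active post 4.223  2.399
#> 2  dance post 9.285  1.414
#> 3 active  pre 5.527  2.028
#> 4  dance  pre 4.726  2.130
```

The planted dance-post effect shows as a near-doubled small-world index and
a much shorter characteristic path length in exactly that cell; with only
two participants per group the interaction test is underpowered (df2 = 2),
which is the point of the full-scale recovery study in the test suite
(22 per group, where the interaction is detected in essentially every
replicate).

Lower-level stages are ordinary functions:

```r
g  <- generate_coupling_graph(512, "smallworld", list(k = 20, p_rewire = 0.1), seed = 7)
ts <- simulate_roi_timeseries(g, fs = 500, duration = 60, coupling_gain = 0.8, seed = 1)
ep <- preprocess(ts)                       # CAR, filter bank, epochs, rejection
mats <- epoch_rwe_matrices(ep)             # per-epoch RWE matrices
nets <- participant_graphs(mats, 10000)    # fixed-density directed graphs
small_world_sigma(nets[[1]], null_ensemble_stats(512, 10000, 100, seed = 2))
```

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --config my_config.json --out results/
```

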