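Package: rweconn
Title: Relative Wavelet Entropy Functional Connectomes from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates directed functional brain networks from multichannel
    resting-state EEG (or cortical ROI) time series using relative wavelet
    entropy between five-band wavelet energy distributions, thresholds them to
    fixed edge counts, and characterises them with small-world, hub and
    functional-cartography graph metrics plus the 2x2 mixed-ANOVA group
    statistics of a pre/post intervention design. Includes a synthetic-data
    generator with known coupling topology for validation, a preprocessing
    stage (common-average reference, Butterworth filter bank, fixed-length
    epoching, amplitude-based epoch rejection), random-graph null ensembles,
    Guimera-Amaral node role assignment, and repeated-measures power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
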