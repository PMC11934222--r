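Package: statesync
Title: State-Resolved Cross-Correlogram Analysis of Cortical Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying synchrony and antisynchrony between pairs
    of cortical neurons across sleep/wake states. Computes per-epoch summed
    cross-correlograms (CCGs), normalizes them against a jitter-equivalent
    triangular-convolution baseline, and summarizes each pair with the
    difference-between-center-and-edges (DCE) statistic and its significance.
    Includes UP/DOWN-state specific analyses (UP-only CCGs, UPnext scrambling
    controls, per-UP spike-phase profiles and profile-based resimulation,
    within-UP spike-timing metrics), burst analysis via two-component log-ISI
    Gaussian mixtures with burst/random spike-removal sweeps, LFP band-power
    modulation analyses (3-h windowed DCE/power correlations, nonREM power
    quartiles, epoch-duration/power relations, DCE temporal-stability
    matrices), and a fully seeded synthetic spike-train/LFP generator with
    ground-truth pair classes for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
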