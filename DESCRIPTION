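Package: prestim
Title: Prestimulus Oscillation Analysis with Phase-Opposition and Cluster
    Permutation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how prestimulus neural oscillations relate
    to trial-by-trial perceptual reports in multi-sensor electrophysiology
    (MEG/EEG-like) experiments. Provides a synthetic-cohort generator with
    injectable ground-truth phase and power effects, a behavioural layer
    with signal-detection criterion estimation, Morlet wavelet
    time-frequency decomposition with a fixed spectral bandwidth rule,
    the phase-opposition-sum (POS) statistic with a two-level (subject and
    group) permutation null, spatiotemporal cluster-based permutation tests
    for POS maps and between-subject brain-behaviour Spearman correlation
    maps, conjunction analysis, percentile bootstrap confidence intervals,
    and circular statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
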