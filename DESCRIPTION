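Package: eegfmrigraph
Title: Static and Dynamic Multi-Modal EEG-fMRI Brain Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted multi-modal brain graphs from concurrent
    EEG-fMRI recordings. EEG channels are reduced to per-band spectral-power
    time courses on the fMRI repetition-time grid and convolved with a
    canonical hemodynamic response function; fMRI independent-component time
    courses are detrended, nuisance-regressed, despiked and band-pass
    filtered. Both modalities are joined into one time-by-node matrix whose
    Pearson correlation matrix is split into non-negative positive- and
    negative-connection graphs, either statically or over sliding windows.
    Provides weighted graph metrics (connectivity strength, clustering
    coefficient, global efficiency), dynamic-series summaries (variance,
    low-frequency fluctuation amplitude, spectra, KPSS stationarity),
    modularity-based connectivity-state detection, group-level
    repeated-measures statistics with FDR control, and a seeded synthetic-data
    generator with known cross-modal coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    signal,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
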