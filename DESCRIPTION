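Package: spikeloc
Title: Spike Source Localization Algorithms and Electrode-Degradation
    Benchmarking
Version: 0.1.0
Authors@R:
    person("spikeloc", "developers", email = "spikeloc@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the position of neurons from extracellular
    multi-electrode recordings and for benchmarking the robustness of those
    estimates against electrode degradation. Implements the three spike
    source localization algorithms in common use on high-density probes --
    center of mass, monopolar triangulation, and grid convolution --
    together with a ground-truth synthetic recording generator
    (point-source forward model on a Neuropixels-like planar probe), a
    denoising and anomalous-channel-detection preprocessing chain
    (causal Butterworth bandpass, common median reference), ground-truth
    waveform and template extraction, and an evaluation harness computing
    accuracy, localization error and estimated drift across progressive
    electrode-degradation sweeps and parameter grid searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    matrixStats,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
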