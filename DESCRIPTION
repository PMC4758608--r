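Package: thetawhisk
Title: Theta-Whisking Coherence Analysis for Rodent Tactile Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of phase coherence between hippocampal theta local field
    potential, the rodent whisking rhythm, and barrel-cortex spiking during
    tactile discrimination behavior. Provides behavioral episode segmentation,
    multitaper and Hanning-taper spectral estimation with shuffle-based
    randomization tests, Hilbert-phase extraction with rank-based bias
    correction, the Phase Synchronization Index (PSI) with bootstrap chance
    levels, trial-level PSI/behavior statistics, and spike phase-locking
    circular statistics (Rayleigh test, von Mises fits, equal-sample
    bootstraps). Includes a synthetic-session generator with coupled phase
    oscillators, von Mises-modulated Poisson spike trains, and planted
    behavioral effect sizes, so that every analysis stage is verifiable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
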