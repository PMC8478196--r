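Package: gammanet
Title: Spiking-Network Models of Cortical Gamma Oscillations and Their
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates conductance-based networks of adaptive exponential
    integrate-and-fire (Adex) neurons implementing the classical gamma
    generation mechanisms (pyramidal-interneuron PING, interneuron-only
    ING, chattering-cell CHING) together with an asynchronous-irregular
    control network. Provides a kernel-based local field potential (LFP)
    synthesis from spike trains, Hilbert-transform gamma-burst detection,
    spike-LFP phase-locking and firing-rate-change statistics (Rayleigh
    and Poisson tests with Bonferroni correction), and stimulation
    protocols measuring network responsiveness, phase-dependent
    responsiveness and resonance in gamma versus asynchronous states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
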