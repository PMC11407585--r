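Package: eventburst
Title: Event-Based Modelling of Eukaryotic Transcriptional Bursting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation and closed-form analysis of eukaryotic
    transcriptional bursting described as a cycle of four promoter events
    (one productive, three silent) with two repetition probabilities.
    Provides an event-driven stochastic simulator with first-order mRNA
    degradation, exact steady-state mean/variance/Fano-factor expressions
    derived from renewal theory, occupancy-dependent regulatory modes with
    gene-regulatory-function, sensitivity and specificity calculations,
    convolution-based transient response curves with overshoot criteria and
    response times, genome-scale constraint scans against a telegraph-model
    comparator, and fitting of event-model parameter trajectories to
    mean-Fano data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
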