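Package: kopmeta
Title: Metastability Analysis of TMS-EEG and a Connectome-Coupled Kuramoto
    Digital Twin
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify how single-pulse transcranial magnetic
    stimulation (TMS) perturbs the coordination dynamics of the brain.
    Implements Kuramoto-order-parameter (KOP) metastability of band-limited
    EEG phases in sliding windows, an evoked-potential-based channel grouping
    algorithm, EEG microstate analysis (TAAHC clustering, Krzanowski-Lai
    model selection, backfitting, transition probabilities) with sliding
    Lempel-Ziv complexity of the microstate label sequence, paired one-tailed
    Wilcoxon signed-rank statistics of pre- versus post-pulse windows, and a
    90-node delayed Kuramoto connectome model ("digital twin") in which a TMS
    pulse is a phase reset that propagates through the network with
    conduction delays.  A synthetic-data module generates EEG cohorts and
    connectomes with planted metastable switching, alpha-dominant spectra,
    microstate-like topographies, and TMS phase-reset effects so that the
    whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    rhdf5,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
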