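Package: meaburst
Title: Burst and Network-Burst Analysis for Microelectrode Array Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of spontaneous activity in multi-electrode array (MEA)
    recordings of cultured neuronal networks. Detects per-electrode bursts by a
    fixed inter-spike-interval rule and network bursts on the pooled spike
    train by an adaptive log-binned ISI-of-six-spikes threshold; computes
    windowed instantaneous firing rates, burstiness and coherence indices, and
    burst-composition statistics; compares experimental groups with a
    Shapiro-Wilk normality gate routing to Welch's t-test or the Conover-Iman
    rank test with Bonferroni correction; and generates synthetic recordings
    with planted network bursts and a chemogenetic-style inhibition
    perturbation so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
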