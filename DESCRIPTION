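Package: crackletrack
Title: Fine-Crackle Acoustics for Discriminating Honeycombing in
    Interstitial Lung Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for fine crackles in digitally recorded
    lung sounds. Detects crackle transients in band-limited inspiratory
    segments, measures the classical time-expanded-waveform parameters
    (two-cycle duration, initial and largest deflection widths, amplitude
    ratios), computes spectral percentile frequencies (F50/F95/F99),
    aggregates per-patient features (crackles per inspiratory phase,
    inspiratory onset-timing tercile), and runs the associated statistical
    chain: median/IQR group summaries with Mann-Whitney and chi-squared
    comparisons, Gwet's AC1 inter-rater agreement, univariate and
    multivariate logistic regression with unit-scaled odds ratios, and ROC
    analysis with the upper-left-corner optimal cutoff. A synthetic-data
    module generates annotated breath-sound audio with ground-truth
    crackles and quartile-calibrated patient cohorts so every stage is
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
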