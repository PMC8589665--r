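Package: bistate
Title: Two-State Analysis of Attentional Bias, Reaction-Time Bimodality,
    and Symptom Imbalance in PTSD
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for linking posttraumatic stress disorder (PTSD) symptom
    structure to attentional-bias measurements.  Implements symptom-cluster
    normalization and harmonization across DSM-IV and DSM-V instruments and
    the avoidance-minus-re-experiencing symptom-imbalance statistic;
    attentional-bias scoring for breaking continuous flash suppression
    (b-CFS) reaction-time data (trial exclusion, matched angry/neutral
    dyads, TAB, AB_TOWARD, AB_AWAY and bias-variability indices);
    Gaussian-mixture bimodality detection with AIC model selection and a
    k-means peak-distance statistic with iterated correlation; one-tailed
    correlation, forward stepwise regression, effect-size and power
    calculations; t-to-z conversion and harmonization for study-level
    region-of-interest meta-analysis; and a synthetic-cohort generator
    built on a two-state Markov model of alternating emotional under- and
    overmodulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
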