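Package: anspm
Title: Autonomic Nervous System Response to Emotional Stimuli via PLS Path Modeling
Version: 0.1.0
Authors@R: person("anspm", "maintainers", email = "anspm@example.org", role = c("aut", "cre"))
Description: Tools to study autonomic nervous system (ANS) engagement during
    emotion-laden audiovisual stimuli. The package extracts heart rate
    variability (HRV) indices from ECG and tonic/phasic features from
    electrodermal activity (EDA) per stimulus epoch, scores recall
    questionnaires on a 0-15 scale, and fits a four-construct partial least
    squares path model (Sympathetic, Vagal, ANS, Recall) with reflective
    indicators, including goodness-of-fit, bootstrap significance of path
    coefficients, and permutation-based multigroup comparison. A synthetic
    data module generates raw biosignals and indicator tables with known
    ground truth so the whole pipeline is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
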