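Package: cbpval
Title: Invasive Validation Pipeline for Cuff-Based Central Blood Pressure Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the invasive validation of non-invasive central blood
    pressure (cBP) estimators built into oscillometric upper-arm cuff devices.
    Provides per-beat analysis of invasive aortic pressure waveforms with
    outlier clearing, hemodynamic-stability and arrhythmia exclusion rules,
    fluid-filled catheter frequency-response quality control from flush tests,
    oscillometric cuff-deflation processing (pulsatile-component separation,
    pulse and foot-point detection, envelope-based brachial estimates, residuum
    artifact scoring) with a pluggable central-pressure estimator, Bland-Altman
    agreement statistics with ARTERY, AAMI, ISO 81060-2 and BHS device grading,
    and a synthetic-cohort generator with known ground truth so the whole
    pipeline can be exercised and tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    signal,
    jsonlite,
    pracma,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
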