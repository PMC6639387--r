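Package: eegslow
Title: Resting-State Prefrontal EEG Slowing Biomarkers and MMSE Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying resting-state, eyes-closed prefrontal
    (Fp1/Fp2) EEG slowing and relating it to global cognition. Implements
    acquisition-style Butterworth filtering, voltage-threshold artifact
    screening, rectangular-window periodogram estimation and the three
    slowing biomarkers (median frequency, peak frequency, alpha-to-theta
    ratio); association statistics (estimated marginal means with
    consecutive contrasts, Pearson and partial correlations with Fisher,
    Zou and Meng comparisons, standardized multiple linear regression,
    intraclass correlation, Bland-Altman agreement); and Mini-Mental State
    Examination (MMSE) score prediction by weighted least squares, ridge,
    elastic-net and LASSO regression tuned over a lambda-alpha grid with
    stratified double cross-validation. A synthetic EEG and cohort
    generator provides reproducible test data with the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    glmnet,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
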