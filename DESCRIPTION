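Package: poincareHRV
Title: Poincare Plot Graphical Metrics and Heart Rate Asymmetry for Short-Term HRV
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of short (5-minute) single-lead ECG recordings
    for heart rate variability (HRV) studies: adaptive Pan-Tompkins R-peak
    detection, RR-interval quality control, smoothness-priors detrending,
    conventional time-domain, frequency-domain and entropy metrics, and a
    Poincare plot graphical metric panel (SD1/SD2 ellipse descriptors,
    |X-50| heart-rate-asymmetry indices PI/GI/SI/AI, and multi-resolution
    grid-occupancy metrics GDR/GDE). A biostatistics layer provides
    normality-gated two-group tests with Cohen's d and confidence intervals,
    covariate-adjusted ANCOVA with partial eta squared, and cross-validated
    ROC analysis. A synthetic-data module generates two-group cohorts with
    controllable oscillatory content, trends, ectopic artifacts and group
    effects so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
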