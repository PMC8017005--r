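Package: predictpd
Title: Likelihood-Ratio Risk Algorithms for Prodromal Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Risk estimation for prodromal Parkinson's disease by
    multiplicative combination of likelihood ratios with a continuous
    age-based prior odds. Implements an enhanced likelihood-ratio
    algorithm with continuous smell (odour-panel logistic score) and
    keyboard-tapping (bivariate Gaussian density ratio over delta
    multiple-of-the-median kinesia score and akinesia time) markers, a
    basic odds-ratio variant, and an MDS-style variant with dichotomous
    markers. Includes conversion of odds ratios to positive and negative
    likelihood ratios given exposure prevalence, a longitudinal cohort
    pipeline with carry-forward imputation across survey waves, risk
    distribution summaries (centiles, fold differences, log-scale
    histograms), a synthetic cohort generator with risk-dependent
    incident disease, and validation statistics (Cox proportional
    hazards on baseline risk, regression of striatal binding on log risk
    with bootstrap confidence intervals).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
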