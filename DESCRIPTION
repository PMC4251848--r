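Package: octostep
Title: Eight-Step Assessment of Statistical and Clinical Significance in Meta-Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing the statistical and clinical significance of
    meta-analytic results in systematic reviews of randomised clinical trials,
    following an eight-step procedure: fixed-effect and random-effects pooling
    with conservative-result selection, heterogeneity diagnostics, multiplicity
    adjustment of significance thresholds, trial sequential analysis with
    diversity-adjusted required information sizes and Lan-DeMets O'Brien-Fleming
    spending boundaries, Bayes factors against the anticipated intervention
    effect, attrition-bias scenario analyses, risk-of-bias subgroup comparisons,
    publication-bias diagnostics (funnel data, Egger, Begg, Harbord, trim-and-fill),
    and a GRADE imprecision cascade. Includes a synthetic review-data simulator
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
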