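Package: multimorb
Title: Model-Based Estimation of Multimorbidity Prevalence from Odds Ratios
    and Marginal Prevalences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesises heterogeneous pairwise disease-association evidence
    into nationally standardised estimates of the prevalence of condition
    combinations. Per-study odds ratios from 2x2 contingency tables are pooled
    by random-effects meta-analysis or, where enough studies exist, by
    meta-regression of the log odds ratio on the product of the study
    prevalences (the expected prevalence of the combination under
    independence). Pooled or predicted odds ratios are then combined with
    national marginal prevalence estimates through a closed-form quadratic to
    recover joint pairwise prevalences, conditional comorbidity profiles and
    expected comorbidity counts, with parametric-bootstrap confidence
    intervals. Includes a synthetic-data generator reproducing the
    healthy-exclusion sampling mechanism that makes observed odds ratios
    depend on study prevalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    metafor,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
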