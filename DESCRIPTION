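Package: certscore
Title: Ceramide Risk Score (CERT1) and Cardiometabolic Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quartile-based ceramide risk scoring (CERT1) of plasma ceramide
    panels (Cer 16:0, Cer 18:0, Cer 24:1, Cer 24:0 and their ratios to
    Cer 24:0), companion clinical scores (HOMA-IR, IDF-style metabolic
    syndrome classification, 2008 Framingham general cardiovascular risk and
    vascular age), and a cohort-level non-parametric statistical pipeline
    (Kruskal-Wallis with Dunn post-hoc tests, multiple linear regression of
    ceramide endpoints on clinical surrogates, rank-transform ANCOVA,
    Spearman correlation, and risk-category contingency analysis). Includes
    a Gaussian-copula synthetic cohort generator that reconstructs
    three-group obesity/metabolic-syndrome study populations from published
    median and interquartile-range summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
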