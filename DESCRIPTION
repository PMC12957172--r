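Package: mmnet
Title: Sex-Stratified Multimorbidity Network Analysis for Diabetes Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and contrasts sex-stratified multimorbidity networks from
    long-format diagnosis records of type 1 diabetes (T1DM) and matched type 2
    diabetes (T2DM) cohorts. Implements disease co-occurrence statistics
    (Salton cosine index, phi coefficient, t-value), a data-driven SCI cut-off
    derivation yielding significant edge sets, weighted network topology
    metrics (degree, weighted degree, density, harmonic centrality, PageRank
    hubs), contrast-based difference networks and subgroup-unique pair
    reports, descriptive summaries with standardized mean differences under
    log-transform rules, 1:1 exact matching on sex and index age, and a
    seeded synthetic EHR cohort generator with planted co-occurrence
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
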