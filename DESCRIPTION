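Package: pantcl
Title: Pan-Subtype Expression Analysis of Mature T-Cell Lymphomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pan-subtype class comparison of mature T-cell lymphoma
    expression profiles against healthy T-cell controls: probe-to-gene
    collapsing, multivariate permutation differential expression with
    Benjamini-Hochberg and Korn-style false-discovery-proportion control,
    cross-subtype signature intersection, the top-scoring-pairs rank
    classifier, CAV1 expression-threshold stratification of tumours,
    correlation-filtered tumour-microenvironment comparison, gene-set
    over-representation and rank-enrichment statistics, and
    immunohistochemistry staining summaries. Includes a synthetic-cohort
    simulator with planted, machine-readable truth and a single-call
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
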