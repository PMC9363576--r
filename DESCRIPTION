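Package: immclust
Title: Immune-Signature Consensus Subtyping of Tumor Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for discovering and validating immune
    molecular subtypes of solid tumors from bulk expression cohorts.
    Tumors are scored against immune gene signatures by single-sample
    gene-set enrichment (ssGSEA), signature scores are screened for
    disease-free-survival association by univariate Cox regression with a
    cross-cohort overlap rule, subtypes are discovered by resampling
    consensus clustering with partitioning around medoids, validated in
    independent cohorts by nearest-centroid projection and the in-group
    proportion, and characterized by tumor-microenvironment scores,
    mutational burden, and weighted co-expression modules. A synthetic
    cohort generator with planted subtype structure makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
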