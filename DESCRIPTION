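Package: maizemet
Title: Multi-Environment Hybrid Maize Trial Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multi-environment randomized complete
    block (RCBD) yield trials of hybrid maize: grain-yield standardization
    to a reference moisture content, per-location RCBD analysis of variance,
    moment-based variance components with broad-sense heritability and
    genotypic/phenotypic coefficients of variation, Student-Newman-Keuls
    means separation with compact letter display, combined
    genotype-by-environment analysis, and rank-based genotype stability and
    environment classification. Includes a synthetic trial generator with
    known variance components so every estimator can be checked by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
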