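Package: morf
Title: Modular Relief Framework for Ranking Genetic Predictors of Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attribute weighting for case-control single nucleotide
    polymorphism (SNP) data with the Relief family of algorithms, organised
    as a modular framework in which a class comparator, a local difference
    function, a global distance and a neighbor weighting kernel can be
    combined freely. Provides the classic algorithms (Relief, ReliefF, SURF,
    SURF*) together with the sigmoid-weighted variant SWRF*, a synthetic
    two-locus epistasis data generator based on penetrance tables with
    controlled heritability and vanishing main effects, and a power
    evaluation protocol (percentile-cutoff success rates, Fisher's exact
    comparisons with Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
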