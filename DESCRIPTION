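Package: metgxe
Title: Multi-Environment Trial Analysis of Genotype-by-Environment
    Interaction and Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-environment variety trials of
    cassava processed-product traits (gari and fufu conversion rates,
    processing losses, fresh and dry root yield). Derives product traits
    from plot-level measurements, fits random-genotype linear mixed
    models by REML to estimate variance components, broad-sense
    heritability (entry-mean and Cullis definitions), BLUPs and
    deregressed BLUPs, builds genotype-by-environment tables of adjusted
    means, fits Finlay-Wilkinson, AMMI and GGE models with total
    sum-of-squares partitioning, and scores genotype stability with
    Wricke's ecovalence and the geometric adaptability index. Includes a
    synthetic trial-data generator with known truth for validating the
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
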