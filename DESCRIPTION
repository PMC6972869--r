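Package: gcnet
Title: Genetic Correlation Networks and Cross-Phenotype Association Tests
    for Multi-Trait GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-phenotype analysis of many quantitative traits
    measured on one genotyped cohort, such as regional brain volumes in an
    imaging-genetics study. Provides a seeded synthetic-cohort generator with
    known genetic ground truth, per-SNP quality control and additive-model
    association scans with covariates, a simplified LD score regression
    estimator of heritability and pairwise genetic correlation, soft-threshold
    power adjacency networks over traits with scale-free model selection,
    topological-overlap dissimilarity and average-linkage module detection,
    and the CPASSOC combined statistics S_Hom and S_Het with Monte Carlo null
    calibration and a beta-distribution tail approximation. A single
    pipeline driver chains all stages deterministically from one seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
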