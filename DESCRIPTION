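Package: genotopics
Title: Topic Modeling of the EHR Phenome and Genotype-Topic Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns disease topics from binary individual-by-phecode matrices
    derived from coded diagnoses using elastic-net regularized non-negative
    matrix factorization, evaluates topic quality and stability (descriptor
    tables, topic dependency, UMass coherence, Hungarian-matched Jaccard
    agreement), and tests topic loadings for association with a single-SNP
    genotype via Pearson correlation and covariate-adjusted logistic
    regression, alongside a conventional per-phecode PheWAS. Ships a
    synthetic-cohort generator with planted latent topics, Hardy-Weinberg
    genotypes and a planted genotype effect so the whole pipeline is testable
    end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
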