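Package: pedscreen
Title: Burden Screening and Family-Based Association for Rare and Common
    Variants in Extended Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates mini-exome family studies (multi-generation pedigrees,
    gene-structured biallelic variants via founder sampling and Mendelian
    gene-dropping, liability-threshold phenotypes with a known causal-gene
    set) and compares eight strategies for detecting trait-associated genes:
    four polygenic burden-screening approaches built on a restricted
    maximum likelihood (REML) variance-components engine with pedigree
    kinship, four family-based association approaches using an orthogonal
    between/within-family genotype decomposition, a Monte-Carlo gene-based
    p-value combiner, hypergeometric pathway over-representation, and
    confusion-matrix evaluation (sensitivity, specificity, PPV, NPV)
    against the simulated causal-gene truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
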