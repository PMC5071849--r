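Package: bisonmix
Title: Admixture Inference for Hybrid-Origin Bison Lineages from Sparse
    Ancient SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests and quantifies the hybrid (steppe bison x aurochs) origin
    of European bison lineages from sparse pseudo-haploid SNP genotypes.
    Provides outgroup-polarized site-pattern counting and ABBA-BABA
    D-statistics with weighted block-jackknife standard errors for ranking
    quartet topologies, f4-ratio estimation of source ancestry proportions,
    a two-topology multinomial simulator driving approximate Bayesian
    computation (rejection sampling with local-linear ridge adjustment and
    leave-one-out cross-validation), a hypergeometric test of shared derived
    alleles distinguishing single from multiple hybridization events, an
    admixture-graph genotype simulator with Balding-Nichols drift for
    validation, and a pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
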