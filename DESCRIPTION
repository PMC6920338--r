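Package: hybridgs
Title: Genomic Selection for Hybrid Breeding with Kinship-Based Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic hybrid breeding: deduce in-silico hybrid
    genotypes from inbred parental SNP panels, filter markers by minor allele
    frequency and missingness, build additive and dominance kinship matrices,
    estimate GBLUP mixed models by eigendecomposition-accelerated restricted
    maximum likelihood, predict phenotypes of untested hybrids through
    partitioned-kinship BLUP, evaluate prediction ability by replicated K-fold
    cross-validation, rank candidate hybrids with a weighted breeding index,
    and estimate broad-sense heritability from replicated block designs. A
    synthetic-data generator emulating inbred parents, crosses and polygenic
    phenotypes makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
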