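Package: mtgblup
Title: Multi-Trait Genomic Prediction with Additive and Haplotype-Based
    Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single- and multi-trait genomic best linear unbiased
    prediction (GBLUP) for diverse crop panels, built around marker-derived
    relationship kernels. Provides an additive (VanRaden) genomic
    relationship matrix, a haplotype-based relationship matrix capturing
    local epistasis within fixed-length SNP windows, and mixed
    genotype-plus-haplotype kernels for GWAS-derived selective marker
    panels. Variance components and genetic correlations are estimated by
    restricted maximum likelihood (single trait) or Gibbs sampling
    (multi-trait models with diagonal, unstructured, or factor-analytic
    genetic covariance, plus two-stage multi-output regressor stacking).
    Cross-validation utilities implement the CV1/CV2/CV3
    phenotype-masking designs used to value auxiliary-trait phenotyping,
    and a seeded simulator generates phased genotypes with tunable linkage
    disequilibrium and multi-trait phenotypes with specified genetic
    covariance so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
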