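Package: hapblockr
Title: Haplotype-Block Based Genomic Prediction
Version: 0.1.0
Authors@R:
    person("hapblockr", "developers", email = "hapblockr@example.org",
           role = c("aut", "cre"))
Description: Partition SNP maps into haplotype blocks by linkage-disequilibrium
    thresholds, fixed marker or base-pair windows, D-prime confidence intervals
    (Gabriel), the four-gamete rule and the solid spine of LD; encode block
    haplotypes as multi-allelic markers; build additive (VanRaden), epistatic
    (Hadamard) and Gaussian kernels; fit GBLUP and extended GBLUP by REML and
    Bayesian LASSO and RKHS kernel-averaging models by Gibbs sampling; and
    evaluate genomic prediction accuracy by random and family-wise
    cross-validation. Includes a forward-in-time simulator of inbred, doubled
    haploid NAM and hybrid crop populations for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
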