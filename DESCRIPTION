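Package: hybridps
Title: Phenomic and Genomic Prediction of Hybrid Values from Parental Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting maize hybrid performance from information
    collected on the parental inbred lines. Builds general and specific
    combining ability (GCA/SCA) relationship kernels from parental SNP
    genotypes, pedigree structure, or near-infrared (NIR) spectra; fits
    multi-kernel BLUP models by restricted maximum likelihood (AI-REML);
    decomposes per-wavelength spectral variance into genetic,
    genotype-by-environment and residual parts via a bivariate polygenic
    model; and evaluates predictive ability under sparse-testing and
    new-family cross-validation scenarios. Includes a seeded synthetic-data
    generator (biparental families, doubled-haploid or selfed line
    derivation, sparse factorials, multi-environment spectra) so the full
    pipeline is testable without access to proprietary breeding data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2,
    withr,
    vcfR
Config/testthat/edition: 3
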