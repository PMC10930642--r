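Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and Mixed-Model GWAS for
    SNP-Array Cattle Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for medium-density SNP-array analysis of livestock
    populations: reading and writing PLINK text and binary genotype files,
    sample and marker quality control with separate GWAS and ROH marker-set
    profiles, detection of runs of homozygosity (ROH) under a consecutive-
    homozygote rule, genomic inbreeding coefficients (F_ROH) overall and by
    ROH length class, ROH-island selection-signature scans from SNP-in-ROH
    frequencies, single-marker GLM and kinship mixed-model (EMMAX-style)
    association scans with principal-component covariates, and a forward
    pedigree simulator that tracks identity-by-descent segments so every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
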