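Package: breedsim
Title: Forward Simulation of Breeding Programs with Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A forward-in-time quantitative-genetics simulator. Starting from
    phased founder genotypes (VCF, diploid or autopolyploid, or a plink-like
    PED/MAP dialect), it simulates meioses on a recombination-breakpoint
    (haplotype block) genome representation, including autopolyploid bivalent
    pairing, X/Y and mitochondrial inheritance and dihaploids; builds complex
    traits from user-specified or gamma-sampled QTN effects with environmental
    variance calibrated to a target broad-sense heritability; and runs
    multi-generation breeding programs with truncation selection on mass,
    pedigree BLUP, GBLUP or single-step GBLUP estimated breeding values over
    configurable SNP chips. Diagnostics include genotype PCA, single-marker
    GWAS with Benjamini-Hochberg FDR, and per-QTN variance decompositions.
    Results are returned as tibbles with tidy(), glance() and autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
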