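Package: wssgblup
Title: Weighted Single-Step Genomic BLUP and Window-Based GWAS for Litter Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trait repeatability animal-model evaluation by pedigree BLUP
    and single-step genomic BLUP (ssGBLUP), with the iteratively SNP-weighted
    variant (WssGBLUP) and its window-based association scan (WssGWAS).
    Provides pedigree parsing and numerator relationship matrices with
    Henderson's sparse inverse, PLINK-text genotype input with call-rate, MAF
    and exact Hardy-Weinberg quality control, VanRaden-style (weighted) genomic
    relationship matrices blended into the single-step H inverse, AI-REML
    variance components with EM fallback, mixed-model-equation solutions with
    prediction-error variances and accuracies, back-solved SNP effects with
    iterative variance re-weighting, sliding-window percentages of genetic
    variance with significance calls and local gene annotation, linkage
    disequilibrium decay curves, and a gene-dropping simulator of
    multi-generation pig pedigrees, genotypes and litter-size phenotypes for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
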