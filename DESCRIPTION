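Package: rohdepress
Title: Runs of Homozygosity, Inbreeding Depression Models and ROH-Status
    Association Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in dense SNP genotype panels
    with a sliding-window caller, computes ROH-based inbreeding coefficients
    (F_ROH, with short/long partitions and leave-one-chromosome-out variants),
    fits binomial mixed models relating inbreeding to a binary fitness
    outcome, runs an allele-specific ROH-status genome-wide association scan
    with an effective-number-of-tests (simpleM) multiple-testing correction,
    and screens phased haplotypes around associated loci for a shared
    recessive haplotype. Includes a pedigree-based cohort simulator with
    controllable inbreeding and an embedded large-effect recessive haplotype
    for method validation, plus PLINK 1 binary genotype input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    jsonlite
Config/testthat/edition: 3
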