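Package: snpsupernet
Title: Genotype-Superset Networks for Case-Control Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds super-node networks from multi-SNP genotype combinations
    (genotype supersets) in case-control and multi-group cohorts, ranks
    markers by a leave-one-SNP-out network-collapse procedure, and assesses
    rank robustness with two genotype-shuffling null models (genotype-count
    preserving and allele-count preserving). Includes the supporting
    association statistics (Yates-corrected chi-square, odds ratios with
    Woolf confidence intervals, one-vs-rest haplotype odds ratios, two-locus
    EM haplotype frequencies and D/D'/r-squared linkage disequilibrium), a
    segregation-curve analysis of shared supersets as a function of SNP
    subset size, Pajek NET export, and a seeded synthetic-cohort generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
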