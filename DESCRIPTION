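Package: msatpop
Title: Microsatellite Population Genetics for Codominant Diploid Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for population-genetic analysis of codominant diploid
    microsatellite genotypes scored from gel band sizes. Reads genotype tables
    in CSV and GenePop formats, calibrates fragment sizes against a DNA ladder
    and bins raw sizes into allele classes, and computes per-breed diversity
    statistics (observed and effective allele counts, observed and expected
    heterozygosity, polymorphic information content, inbreeding coefficients),
    hierarchical F-statistics with the island-model gene-flow transform,
    Ewens-Watterson homozygosity neutrality deviates (exact partition
    enumeration or seeded Monte Carlo), and per-locus UPGMA dendrograms from
    Nei's standard distance or Dice band sharing. A seeded Balding-Nichols
    simulator generates genotype datasets and band tables with a target
    differentiation level so every stage of the pipeline can be exercised.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
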