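Package: fadsevo
Title: Evolutionary Analysis of the FADS Haplogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolutionary history of the fatty acid
    desaturase (FADS) haplogroup region: a forward-in-time Wright-Fisher
    simulator of a biallelic locus under a founding bottleneck with
    time-limited codominant selection (with an exact Markov-chain fixation
    oracle and full fixation-proportion parameter grids), a population branch
    statistic (PBS) selection scan with genome-background Z-scores and
    Bonferroni-corrected p-values, an outgroup-calibrated TMRCA estimator for
    the derived haplogroup with infinite-sites filtering and sensitivity
    analysis, tag-SNP haplogroup classification with core-haplotype consensus
    strings and opposite-fixation detection, haplotype networks and
    bootstrapped neighbor-joining trees, and a latitude-cline regression with
    an empirical genome-wide outlier test. A synthetic-data module generates
    phased haplotype alignments, three-population allele-count panels and
    cline tables with known truth so every stage is testable without cohort
    genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
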