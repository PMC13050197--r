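Package: tetrasegvar
Title: Segregation Variance Prediction for Autotetraploid Bi-Parental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form prediction of the additive segregation variance of
    F1 families from bi-parental crosses in autotetraploid, heterozygous
    clonal species such as potato. Given phased (or unphased) parental
    genotypes, a genetic map and additive marker effects, the package
    computes the expected genetic variance among progenies from the
    linkage-disequilibrium structure of the parental haplotypes under
    bivalent meiosis, with optional double-reduction and finite-family
    corrections. It also provides the exact two-locus gamete and progeny
    probability model used as a brute-force oracle, a forward simulator of
    autotetraploid bivalent meiosis, progeny-based variance estimators, and
    a scenario runner to study how family size, family-size distribution
    and family number affect prediction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
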