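Package: ssrinvasion
Title: Microsatellite Population Genetics and Invasion-Route Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for diploid microsatellite (SSR)
    population genetics, built around the analyses used to characterise
    recently introduced, bottlenecked plant populations: per-locus and
    per-population diversity statistics (Na, Ho, He, FIS, rarefied allelic
    richness, private alleles), Guo-Thompson Markov chain exact tests of
    Hardy-Weinberg equilibrium, EM estimation of null-allele frequencies with
    ENA-corrected FST, AMOVA with permutation significance, pairwise
    Weir-Cockerham FST, Mantel tests with exact enumeration for small label
    sets, directional relative-migration networks, BIC-selected k-means
    clustering with DAPC, principal coordinates analysis, Nei-distance UPGMA
    trees with locus bootstrap, and a compact approximate Bayesian computation
    engine that simulates SSR data under user-defined invasion scenarios
    (divergence, bottleneck, admixture) with a stepwise mutation model
    coalescent. A synthetic-data module generates island-archipelago style
    genotype fixtures with known truth so the whole pipeline runs without any
    external data.
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
    jsonlite,
    MASS,
    nnet,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
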