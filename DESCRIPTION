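Package: ystrpop
Title: Y-Chromosome STR Haplotype Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic analysis of Y-chromosome short
    tandem repeat (Y-STR) haplotypes: reading and validating Yfiler-panel
    haplotype tables, Bayesian allele-frequency haplogroup prediction, Nei
    haplotype diversity with bootstrap confidence intervals, Slatkin R_ST
    distances and analysis of molecular variance (AMOVA) under the stepwise
    mutation model with permutation significance, island-model migration
    rate conversion, nonmetric multidimensional scaling of distance
    matrices, weighted median-joining haplotype networks with maximum
    parsimony pruning, rho-statistic TMRCA estimation, and a forward-time
    Wright-Fisher simulator of multilocus STR haplotypes under founder
    events, regional subdivision, migration and admixture pulses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    boot,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
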