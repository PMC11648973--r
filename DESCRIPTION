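Package: popdrift
Title: Wright-Fisher Drift Simulations and the Detectability of Hatchery Ancestry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of pure genetic drift across
    isolated populations founded from a common source, together with the
    analysis chain used to ask how quickly drift makes hatchery-founded
    populations look distinct: genepop input/output and genotype filtering,
    diversity statistics (rarefied allelic richness, heterozygosity, FIS),
    Weir-Cockerham FST, Nei's DA distance with neighbor-joining trees and
    bootstrap support, Mantel isolation-by-distance tests,
    linkage-disequilibrium effective population size estimation (Burrows'
    composite measure with Waples' bias correction), a maximum-likelihood
    admixture model fitted by EM with cross-validated selection of the number
    of clusters, label-switching alignment of ancestry matrices, and nested
    beta regressions with AICc model selection relating mean cluster
    assignment to effective size and generations of drift.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
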