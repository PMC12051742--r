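Package: crowdemog
Title: Demographic Model Comparison and Introgression Statistics for
    Secondary-Contact Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to discriminate a genome-wide swamping history from a
    locus-specific introgression history in four-population
    secondary-contact systems, exemplified by the European crow hybrid
    zone. Implements a structured-coalescent simulator for independent
    non-recombining loci under isolation-with-migration models with
    exponential growth, folded joint site-frequency-spectrum
    composite-likelihood fitting with ECM-style cyclic optimisation and
    AIC model choice, parametric bootstrap with bias correction,
    topology weighting of block gene trees with ternary binning, and
    windowed population-genetic statistics (pi, dXY, Hudson FST, net
    divergence, Tajima's D, Patterson's D, f4-ratio, fdM, four-gamete
    fraction). A synthetic-data generator emulates the study design,
    including a migration-resistant barrier locus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
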