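Package: dompopgen
Title: Population Genetics for Dominant (Presence/Absence) Marker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dominant molecular markers (ISSR, RAPD,
    AFLP) scored as binary band matrices: per-primer informativeness
    statistics (PIC, resolving power, marker index), within-population
    diversity under band-state and dominant-HWE allele-frequency models,
    analysis of molecular variance (AMOVA) with permutation-tested overall
    and pairwise Phi-ST, Nei diversity partitioning with Hedrick and Jost
    corrections, Nei genetic distances, principal coordinate analysis,
    Mantel isolation-by-distance testing, and a Bayesian admixture model
    (Gibbs sampler) with Evanno delta-K cluster-number selection. Includes
    a Balding-Nichols simulator of structured dominant-marker datasets with
    known truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
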