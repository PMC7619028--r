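Package: resevo
Title: Predicting Pesticide Resistance Evolution from Single-Generation Fitness Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a hybrid experimental-theoretical analysis of pesticide
    resistance evolution in selfing laboratory populations. Fits inverse-sigmoid
    dose-survival curves to plate-assay counts and derives EC50 values, computes
    per-genotype fitness as normalised fecundity times survival under compound
    selection, runs a stochastic Wright-Fisher forward simulator of resistant
    allele frequency at constant population size, and estimates selection
    coefficients and relative fitness from multi-generation frequency
    trajectories by logit-linear regression. A synthetic-data generator emulates
    the dose-survival, fecundity and competitive microevolution study designs so
    the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
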