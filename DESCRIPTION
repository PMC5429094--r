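Package: mutevol
Title: Mutation-Rate Dynamics in Stressed Microbial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of dynamic mutation-rate evolution in
    microbial populations under severe stress. Implements Luria-Delbruck
    fluctuation-assay mutation-rate estimation by Ma-Sandri-Sarkar maximum
    likelihood with Stewart or profile-likelihood confidence intervals,
    Gompertz growth-parameter extraction (lag time, specific growth rate,
    carrying capacity, doubling time), competition-assay relative fitness
    with fluorescence-loss correction and rounds-to-fixation prediction,
    exponential death-rate estimation from viable-count decay, lineage
    accounting (generations per transfer cycle, effective population size),
    trajectory-level rank correlations and mutational-spectrum tallies, and
    seeded synthetic-data generators for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
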