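Package: segpred
Title: Genomic Prediction of Trait Segregation in Progeny Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the segregation of quantitative and ordinally scored
    traits in F1 progeny populations from genome-wide multi-allelic marker
    data of candidate parents. Marker effects are estimated with a Bayesian
    shrinkage regression (BayesA) extended with a latent-variable threshold
    model for ordinal scores, fitted by Gibbs sampling. Marker segregation
    in candidate crosses is simulated from phased parental haplotypes and a
    linkage map using Haldane's map function, and the posterior distribution
    of the proportion of progenies fulfilling multi-trait selection criteria
    is computed to rank crosses and choose progeny population sizes. Includes
    a synthetic-data generator emulating a perennial fruit-tree breeding
    panel and a simulation study for validating proportion predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
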