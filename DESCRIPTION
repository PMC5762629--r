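Package: sparrowdiv
Title: Phenotypic Versus Neutral Genetic Differentiation (Pst-Fst) for
    Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for contrasting phenotypic divergence (Pst) with neutral
    genetic differentiation (Fst) across structured populations typed at
    microsatellite loci. Implements Weir-Cockerham theta with bootstrap
    confidence intervals and permutation tests, hierarchical AMOVA on gene
    copies, rarefied allelic and private allelic richness, Monte Carlo exact
    Hardy-Weinberg tests, a moment estimator for null alleles, a
    heterozygosity-excess bottleneck test under the two-phase mutation model,
    Mantel tests for isolation by distance, reflectance-to-brightness
    conversion, behavioral assay scoring, Bayesian variance-component
    estimation by Gibbs sampling, and the Pst-Fst decision framework with
    critical c/h2 values. A synthetic-data module generates datasets with
    known ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    geosphere,
    car,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    lme4
Config/testthat/edition: 3
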