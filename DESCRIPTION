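Package: offsetforest
Title: Truth-Known Evaluation of Gradient-Forest Genomic Offset Predictions
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of a spatial
    metapopulation with explicit genotype-phenotype-fitness maps (neutral,
    single-locus, and polygenic two-trait architectures), a gradient-forest
    style turnover-function engine producing genomic offset ("GF Offset"),
    competing offset metrics (pairwise Weir-Cockerham FST and environmental
    distances), and an in silico reciprocal-transplant assessment that
    correlates each offset measure with common-garden fitness. Because the
    simulations provide full knowledge of causal loci, environments, and
    fitness, the package supports truth-known evaluation of genomic offset
    as a predictor of maladaptation under environmental change.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    MASS,
    Matrix,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
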