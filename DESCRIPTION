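Package: screenfit
Title: Fitness Inference and Population-Genetic Analysis of Pooled
    Variant Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for massively parallel variant-fitness screens in
    microbial populations. Infers per-variant selection coefficients from
    barcode read-count trajectories with a hierarchical Bayesian model
    anchored on non-editing neutral barcodes (variational or MCMC engines),
    classifies variants by posterior credible intervals, and follows up with
    population-genetic analyses on a strain-by-variant genotype panel:
    allele-frequency-matched neutral controls, Jaccard co-occurrence
    bootstrap tests, singleton-based strain-age comparisons, Fitch parsimony
    and retention index on a phylogeny, per-strain enrichment of beneficial
    variants across domesticated and wild clades, and a clade-random-effect
    mixed model of ecological origin. Includes simulators for serial-dilution
    competition experiments, clade-structured populations, and protein
    alpha-carbon chains, so every stage is testable against known ground
    truth, plus a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    bio3d,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
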