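Package: popgensel
Title: Selection and Demographic Inference from Two-Population Site
    Frequency Spectra
Version: 0.1.0
Authors@R: person("popgensel", "maintainers", email = "popgensel@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying natural selection in two diverged
    populations from genome-wide polymorphism data. Builds, projects and
    folds one- and two-population site frequency spectra from diploid
    genotype calls; computes expected spectra under an
    isolation-with-migration demography with exponential size change and
    per-mutation scaled selection, via a finite-volume diffusion solver
    cross-validated against an exact Wright-Fisher transition-matrix
    oracle; fits mixture distributions of fitness effects (point mass,
    exponential, normal, gamma, each optionally with a lethal point mass)
    to folded non-synonymous spectra by Poisson random-field likelihood
    with bootstrap confidence intervals; computes McDonald-Kreitman
    statistics and classifies genes as negatively selected, neutral or
    positively selected with a Bayesian Poisson random-effects model;
    and provides identity-by-state allele-sharing matrices, mtDNA summary
    statistics, a synthetic-data generator for every input, and a
    config-driven pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
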