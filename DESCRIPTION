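Package: IBDemog
Title: Demographic Inference from IBD and ROH Segment Length Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates founder-event (bottleneck) parameters from the
    length spectrum of identity-by-descent (IBD) segments shared between
    modern genomes and runs of homozygosity (ROH) within modern and
    ancient genomes. Implements discrete-generation pairwise coalescence
    distributions for piecewise single-population and two-subpopulation
    split/merge demographies (including ancient sampling times and
    consanguinity), closed-form expected segment counts per genetic-length
    bin, a Poisson composite likelihood with a per-pair joint objective,
    differential-evolution maximum-likelihood fitting with parametric
    bootstrap confidence intervals and bootstrap likelihood-ratio model
    selection, a synthetic-data generator with a Monte-Carlo segment-level
    oracle, ROH table post-processing rules, and auxiliary founder-population
    statistics (binomial founder-allele simulations, exact tests, and a
    continuous gene-flow bound).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
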