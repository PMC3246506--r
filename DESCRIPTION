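Package: perceptsim
Title: Individual-Based Simulation of Perceptron-Encoded Niche Preference
    Evolution and Sympatric Speciation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time, individual-based simulation of a diploid,
    sexually reproducing population of resource "exploiters" whose niche
    preference is encoded by a genetically specified feed-forward perceptron
    (two sensory inputs, three hidden nodes, one output). Thirteen real-valued
    weight loci on a chromosome pair are expressed codominantly and map each
    genotype to a response array over four resource niches; reproductive
    output and density-dependent competition translate preference into
    fitness. An unlinked biallelic mating gene switches individuals between
    random and niche-assortative mating, allowing the emergence of
    reproductive isolation to be studied. The package provides the full
    generation loop (mating pools, pair formation, gamete formation with
    crossover and point mutation, phase-scheduled mutation control), logging
    and snapshot serialisation, and the accompanying analysis toolkit:
    phenotype classification, unfit-phenotype statistics, the
    likelihood-ratio (maximum-likelihood chi-square) G-test, a
    mutation-robustness resampling assay, PCA-based haplotype and genotype
    clustering, and running-average trajectory smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    cluster
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
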