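Package: phylocov
Title: Phylogenetic Coverage and the Drivers of Diversity Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools to study how the phylogenetic
    breadth of a community dataset shapes the support for drivers of
    species-richness gradients. Includes a multi-state
    speciation-extinction (MuSSE-type) Gillespie simulator with
    temperature-dependent speciation and stepwise niche transitions,
    subclade extraction and classification of richness-temperature
    relationships, a taxa-pooling coverage analysis based on AICc-weighted
    all-subsets model averaging of standardized effect sizes, a synthetic
    elevational-gradient community generator with known driver structure,
    and a discrete-generation community model of negative density
    dependence with antagonist spillover scored by Shannon diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
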