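Package: phytonet
Title: Network-Based Prediction of Phytochemical Health Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated in silico pipeline for predicting potential health
    benefits of phytochemicals. Propagates direct and indirect molecular-target
    effects over a protein-protein interaction network with a random walk with
    restart, aggregates node scores to phenotypes, and selects significant
    phenotypes against an empirical permutation null. Predicted effects are
    filtered by physicochemical availability (Lipinski rule of five, intestinal
    absorption, Caco-2 and blood-brain-barrier flags) and matched against
    ethnopharmacological uses of the plants containing each compound via
    Wu-Palmer semantic similarity on a phenotype concept hierarchy. Includes
    literature co-occurrence validation statistics (Jaccard index, Fisher exact
    enrichment, Benjamini-Hochberg FDR, Mann-Whitney tests), skew-controlled
    precision/recall evaluation, and deterministic synthetic-fixture generators
    for every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
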