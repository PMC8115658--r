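Package: nbgwas
Title: Neighbor Effects in Genome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association mapping of neighbor (associational)
    effects among spatially arranged individuals. Extends the standard
    kinship linear mixed model with a neighbor genotypic-identity covariate
    and a second variance component, following the inverse problem of a
    two-dimensional Ising model. Provides AI-REML variance-component
    estimation, an eigendecomposition-accelerated association scan with
    forward-selection likelihood-ratio tests for self, neighbor, and
    asymmetric neighbor effects, variance partitioning (single, partial,
    and net proportions of variance explained) with effective spatial-scale
    estimation, a calibrated phenotype simulator for power evaluation
    (ROC/AUC, sensitivity, effect-size error), and simulated annealing of
    allele arrangements that minimize or maximize the population phenotype
    sum.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
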