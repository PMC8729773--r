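Package: dysbionet
Title: Diet-Induced Gut Microbiome Dysbiosis: Dispersion, Beta-Diversity
    Partitioning, Co-Occurrence Networks and Their Robustness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for diet-induced dysbiosis studies of the
    insect gut microbiome. From an OTU count table with diet and
    developmental-stage metadata it computes Bray-Curtis ordination
    (PCoA), multivariate dispersion (PERMDISP), the decomposition of
    pairwise beta diversity into similarity, replacement and
    richness-difference components, ternary OTU coordinates, signed
    OTU-OTU co-occurrence networks with permutation-renormalization
    null models, network topology summaries with hub and keystone
    classification, and network robustness under stepwise node-removal
    attacks. Also includes bioconversion bioassay metrics (substrate
    reduction, ECI, WRI) and a synthetic data generator with a planted
    ground-truth association network so every stage of the pipeline can
    be tested without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
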