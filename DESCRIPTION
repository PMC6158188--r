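Package: fluxomix
Title: Multi-Omics Analysis of Oxygen-Limited Fungal Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based flux simulation and omics statistics for
    fed-batch fermentations with an oxygen-limitation switch, modelled on
    industrial enzyme production by Aspergillus niger. Provides flux
    balance analysis (FBA) and parsimonious FBA over genome-scale or toy
    metabolic models read from SBML or a TSV dialect, with measured
    specific rates (glucose, oxygen, product, by-products, ATP
    maintenance) applied as per-phase constraints; PCA and NIPALS partial
    least squares with variable-importance-in-projection (VIP) screening
    of metabolite pool sizes against the specific oxygen uptake rate;
    fuzzy c-means clustering of expression time courses with directional
    gene-set analysis and hypergeometric over-representation tests; and
    seeded synthetic-data generators (toy networks with provable optima, a
    simulated fermentation, planted omics matrices) so the whole pipeline
    runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    e1071,
    mclust,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
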