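Package: pigmentax
Title: Pigment-Based Chemotaxonomy of Lake Phytoplankton Communities
Version: 0.1.0
Authors@R:
    person("Pigmentax", "Developers", email = "pigmentax@example.org",
           role = c("aut", "cre"))
Description: Tools for High-Performance Liquid Chromatography (HPLC)
    phytoplankton pigment analysis in lakes: dataset quality assurance via
    the Aiken internal-consistency criteria, CHEMTAX-style constrained
    ratio-matrix factorization of pigment concentrations into taxon-group
    biomasses expressed as total chlorophyll a, diagnostic-pigment
    size-fraction proportion factors, principal component analysis of
    pigment ratios via singular value decomposition, Ward hierarchical
    clustering on Pearson correlation distance, weighted pigment
    correlation networks with soft thresholding and Louvain community
    detection, seasonal analysis of variance with Tukey comparisons, and a
    calibrated synthetic-data generator with hidden ground truth for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    quadprog,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
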