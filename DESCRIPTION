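Package: lipidtraffic
Title: Lipid Traffic Analysis of Multi-Tissue Lipidomics Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A network analysis of lipidomics data that compares the spatial
    distribution and abundance of lipid variables across connected tissue
    compartments between two phenotypes. Classifies every lipid as A-, B- or
    U-type per network scope (switch analysis), quantifies between-phenotype
    differences in presence lists with Jaccard-Tanimoto coefficients and
    permutation p-values, and computes error-normalised fold changes (ENFC)
    at class, species and subclass level. Includes a synthetic-data generator
    that plants known traffic patterns with a machine-readable ground truth,
    so the whole analysis is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
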