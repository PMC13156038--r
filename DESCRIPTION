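Package: neuropepmap
Title: Regional Mapping of Neuropeptide Receptor Systems in the Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the regional organization of neuropeptide
    receptor systems from parcellated brain data. Provides quality-control
    filtering and robust-sigmoid normalization of regional gene-expression
    tables, donor aggregation and differential stability, spatial
    autocorrelation statistics (Moran's I, empirical variograms) together
    with two null models for map-level inference (variogram-matched
    surrogate maps and matched-gene null sets), dominance analysis for
    receptor colocalization, partial least squares correlation with
    permutation, bootstrap and cross-validation, principal component
    profiling of nuclear expression profiles, and summary statistics for
    evolutionary substitution-rate tables. A synthetic-data module
    generates spatially autocorrelated regional maps, gene pools,
    multi-donor expression stacks and paired map sets with planted latent
    structure so every stage can be exercised end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
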