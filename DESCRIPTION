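Package: imcniche
Title: Spatial Niche Analysis for Segmented Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell spatial analysis of segmented multiplexed imaging data
    (e.g. imaging mass cytometry) built around the histomorphic niches of
    schwannoma tissue: per-cell quantification from label masks with one-pixel
    expansion, percentile normalisation and batch-balanced graph clustering
    into cell populations, cross-pair correlation functions with permutation
    significance, adjacency cell-contact networks, Gaussian-mixture cellular
    neighbourhoods with Fowlkes-Mallows stability selection, neighbourhood
    proximity enrichment, permutation-based receptor-ligand scoring, and
    normality-gated group statistics. Ships a synthetic tissue generator that
    emulates dense organised (Antoni A-like) and sparse (Antoni B-like)
    regions so the whole pipeline is testable without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    igraph,
    mclust,
    Matrix,
    deldir,
    RANN,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
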