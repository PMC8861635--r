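Package: ctgenome
Title: Circuit Topology Analysis of Genome Folds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolbox for circuit-topology analysis of folded chromatin chains.
    Classifies every pair of intra-chain contacts as series, parallel, cross or
    concerted, builds topology matrices from 3D bead-chain models or Hi-C count
    maps, and derives higher-order topological descriptors: the entangled
    fraction and its projection onto genomic sequence, the trefoil-based
    network clustering coefficient, the box-counting (Minkowski-Bouligand)
    fractal dimension of the topology matrix, cumulative-window length-scale
    scans with peak detection, and L-pattern/L-loop motif profiles with
    segment barcodes. Includes a constrained lattice random-walk null model,
    synthetic fixture generators, and the statistical test-selection logic
    used for group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    car,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
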