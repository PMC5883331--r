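Package: transcortex
Title: Coupling of Cortical Structural Covariance and Transcriptional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to build and compare structural covariance networks
    (inter-regional correlation of cortical thickness across subjects) and
    transcriptional brain networks (inter-regional correlation of regional
    gene expression profiles) on a common cortical parcellation. Includes
    mapping of scattered post-mortem expression samples to parcels with a
    sub-cortical distance tolerance, probe-to-gene collapsing, density
    thresholding of correlation matrices, a graph-topology battery with
    degree-preserving rewired nulls (clustering, path length, efficiencies,
    small-worldness, assortativity, rich club, participation coefficient),
    Louvain community detection with consensus clustering, a spatially
    contiguous module-permutation null, distance-decay model selection by
    AIC, gene-set expression indices (including the 19-gene human
    supragranular enriched set), and edge-wise coupling statistics between
    covariance and co-expression. A synthetic cortex generator with planted
    modular covariance, spatially autocorrelated expression and a planted
    coupled gene set makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
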