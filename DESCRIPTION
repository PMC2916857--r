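Package: morphoforge
Title: Generative Modelling and Analysis of Neuronal Branching as Optimized Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for representing, analyzing, generating and reconstructing
    neuronal dendritic trees as rooted geometric graphs. Implements a canonical
    tree representation (hierarchical label sorting, equidistant resampling with
    cable-length conservation, electrotonic-equivalent layout and a
    one-dimensional "topological gene" encoding), an extended minimum spanning
    tree growth algorithm in which a single balancing factor weighs Euclidean
    wiring cost against conduction-time (path length) cost, samplable spatial
    density fields for carrier points, steady-state passive electrotonic
    signatures by conductance-matrix inversion, morphometric statistics (branch
    order, Sholl intersections, path-length distributions), competitive
    multi-tree growth producing dendritic tiling, cosmetic post-processing
    (spatial jitter, diameter taper, soma mapping), and model-based automated
    reconstruction of trees from three-dimensional image volumes, including a
    synthetic fluorescence volume renderer for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'tree-core.R'
    'canonical.R'
    'electrotonics.R'
    'morphometry.R'
    'fields.R'
    'growth.R'
    'postprocess.R'
    'reconstruct.R'
    'RcppExports.R'
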