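Package: namdclust
Title: Unsupervised Conformational Analysis of Nonadiabatic Molecular
    Dynamics Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to ingest ensembles of surface-hopping molecular dynamics
    trajectories (multi-frame XYZ geometry series with per-frame electronic
    properties), convert geometries into translation- and rotation-invariant
    descriptors (pairwise-distance vectors, Z-matrix internal coordinates,
    Cremer-Pople ring-puckering parameters, SOAP power spectra), scale and
    resample the resulting feature tables, embed them with PCA, ISOMAP or
    t-SNE, partition conformations with K-means, Gaussian mixtures,
    hierarchical or spectral clustering (including automatic selection of the
    cluster number), and summarise electronic properties per cluster to
    expose mechanistically distinct regions such as hopping versus
    non-hopping geometries.  Includes a synthetic-ensemble generator with
    planted conformer classes and hop events for end-to-end validation, and
    a command-line pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    cluster,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
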