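Package: knotph
Title: Persistent Homology Pipeline for Open Knotted Protein Backbones
Version: 0.1.0
Authors@R: person("knotph", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse the entanglement of open protein backbone curves
    with degree-1 Vietoris-Rips persistent homology. Builds interpolated
    C-alpha point clouds from PDB files or from a built-in generator of open
    trefoil curves, computes persistence diagrams with representative cycles
    over Z/2, converts diagrams to exact piecewise-linear persistence
    landscapes, compares structures with the W1[L-infinity] Wasserstein
    distance and landscape L1 distances, tests group differences with a
    label-randomization test on average landscapes, embeds distance matrices
    in two dimensions with Isomap, and localizes the entangled region of a
    knotted curve via the representative cycle of a discriminating landscape
    peak.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
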