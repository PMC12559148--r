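Package: synchropat
Title: Synchrony-Breaking Bifurcation Analysis of Cell-Communication Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the preferred cell-fate pattern of a regular
    cell-communication network from its adjacency spectrum together with
    qualitative features of the linearized internal (Q) and coupled (R)
    cell dynamics.  Provides lattice network builders, reduced-matrix
    Jacobian spectra via the Kronecker decomposition, balanced-coloring
    machinery for polysynchrony subspaces, a classifier for first
    synchrony-breaking bifurcations (one- and two-species cells with
    singular coupling), parameter continuation with first-crossing
    detection, lateral-inhibition (Delta-Notch type) simulation fixtures,
    and inverse inference of sign constraints on biochemical interactions
    from an observed pattern class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
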