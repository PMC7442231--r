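Package: epimotifs
Title: Template-Based Mapping of Dynamic Cell-Rearrangement Motifs in
    Epithelial Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies dynamic multicellular motifs
    (T1 neighbour exchanges, reversing T1s, multicellular rosettes and
    rosette hubs) in tracked epithelial movies.  A user-supplied example
    of a motif is converted into a feature time series and matched
    against every tracked group of k connected cells by open-ended,
    constrained dynamic time warping; graph-theoretic pruning of the
    candidate space and a 1-nearest-neighbour classifier separate true
    events from look-alikes.  Includes conversion of tracked label-image
    movies into a polygonised tissue representation with cell adjacency,
    downstream statistics (motif frequency with boundary correction,
    junction kinetics and orientation, circular tests), and a vertex-model
    simulator of a planar epithelium that generates ground-truth
    rearrangement events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
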