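Package: MotionDissect
Title: Function-Specific Collective Motions in Multi-Signaling Receptor
    Complexes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and dissects function-specific collective motions in
    receptor complexes that signal through more than one downstream pathway.
    Low-frequency normal modes are computed for wild-type and variant
    structures from a pluggable Hessian (default: anisotropic elastic
    network model), each mode's motion is fingerprinted as a C-alpha
    distance-difference matrix, fingerprints are compared across systems by
    Mantel permutation tests, and motions are classified as shared or
    system-unique given phenotype annotations.  Each motion class is then
    characterised by dynamic cross-correlation maps, group flexibility
    profiles, weighted residue interaction networks with Girvan-Newman
    communities, betweenness centralities, suboptimal path ensembles with
    node degeneracy, and hydrogen-bond/salt-bridge occupancy differences.
    Includes a synthetic-fixture generator producing coarse-grained
    multi-chain complexes with engineered, known motion structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
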