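Package: crowdfold
Title: Coarse-Grained Langevin Simulation of Protein Folding in a Crowded Cell
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A two-particle-per-residue (C-alpha plus side-chain centroid)
    protein model driven by Langevin dynamics with a spring-based force field
    and a hybrid implicit-explicit solvent in which drag and directional
    solvent kicks act only on solvent-exposed surface, biased toward
    hydrophobic side chains so that hydrophobic collapse emerges without any
    knowledge of the native state.  Includes co-translational synthesis from
    a ribosome sphere into a crowded spherical cell with hard-sphere
    crowding agents at a target excluded-volume fraction, a consensus
    contact-map structure-prediction protocol with diversity-filtered
    selection, and trajectory observables (TM-score, largest alignable
    fraction, relative radius of gyration, conformational fixation time,
    native-like time).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    yaml,
    jsonlite,
    zoo,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
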