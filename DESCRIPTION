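Package: knotpore
Title: Coarse-Grained Simulation of Nanopore Unzipping of Knotted DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates driven translocation and strand unzipping of knotted
    double-stranded DNA through a slab-embedded cylindrical nanopore, using a
    simplified two-strand bead-spring ladder model with breakable base pairing
    evolved by Langevin dynamics. Provides a synthetic-setup stage (Monte Carlo
    sampled semi-flexible chains, tight parametric knotted leads, threaded
    single-stranded lead, pinned relaxation), a knot toolkit (KMT
    simplification, minimally interfering chain closure, Alexander-determinant
    classification, bottom-up knot localization and composite decomposition),
    and a trace pipeline (translocation traces, knot kymographs, knot-length
    series, velocity-regime detection, heterogeneity ratios, strand-wrapping
    turns), together with extended-XYZ trajectory and YAML configuration I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
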