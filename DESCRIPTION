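Package: tdcsim
Title: Voxel Finite-Element Simulation and Electrode-Montage Optimization
    for Transcranial Direct Current Stimulation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the quasi-static electric field induced in the head by
    transcranial direct current stimulation (tDCS) and optimizes the scalp
    electrode montage for targeted cortical regions. Solves the
    volume-conduction equation div(sigma grad phi) = i with homogeneous
    Neumann boundary conditions on conductivity-labelled voxel models using
    first-order cubical finite elements and a preconditioned conjugate
    gradient solver, samples the field magnitude on a surface 1 mm below the
    gray-matter boundary, and ranks candidate 10-10 midline montages by the
    mean field strength over bilateral primary motor cortex and supplementary
    motor area regions of interest. Ships a synthetic layered-sphere head
    phantom generator with population-level anatomical variability and a
    closed-form Legendre-series solution for layered spheres that serves as
    an independent verification oracle, plus a conductivity sensitivity
    analysis for bone and cerebrospinal fluid.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
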