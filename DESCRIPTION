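Package: trimerscope
Title: Geometry and State-Occupancy Analysis of Trimeric Elevator Transporters in Lipid Nanodiscs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of structural ensembles of homotrimeric
    elevator-type transporters (glutamate transporter homologues such as
    Glt_Tk and Glt_Ph) embedded in lipid nanodiscs. Provides rigid-body
    Kabsch superposition and RMSD, estimation of the pseudo-three-fold axis
    of the trimer and reorientation into that frame, per-protomer gate
    (HP1/HP2 tip) and elevator-displacement measurements with discrete
    state classification, height-versus-perimeter buckling profiles of the
    nanodisc membrane-scaffold (belt) protein, and an equilibrium
    binding-occupancy model (single-site with ligand depletion) with
    binomial/multinomial distributions of protomer states fitted to
    observed particle-class counts. Includes a deterministic generator of
    synthetic trimer-plus-belt coordinate fixtures with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
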