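Package: dendrisurf
Title: Coarse-Grained Langevin Dynamics and Aggregate Analysis of
    Dendrimer-Surfactant Complexation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implicit-solvent, reduced-unit Langevin dynamics of terminally
    charged cationic dendrimers complexing with anionic surfactants and
    mobile counterions, together with the complete aggregate taxonomy used to
    analyse such trajectories: surfactant micelle detection under periodic
    boundaries, bridge/corona classification of dendrimer-bound micelles,
    mixed-cluster labelling, counterion condensation counts, aggregate
    indexing, ensemble histograms with occurrence-based reliability
    filtering, favored-cluster identification and effective-charge analysis.
    Includes a planted-configuration generator for validating every analysis
    stage against known ground truth, and readers/writers for LAMMPS data
    and dump text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
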