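Package: hepnmr
Title: NMR-Guided Analysis of Protein-Heparin Oligosaccharide Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing protein-glycosaminoglycan interactions from
    solution NMR data: chemical-shift-perturbation titration analysis with one-site
    Kd fitting and nonlinear peak-migration detection, a sequential two-site binding
    simulator for fast-exchange shift trajectories, a heparin oligosaccharide 3D
    builder with controlled ring puckers, sulfation patterns and glycosidic torsions
    (including selective desulfation variants), compilation of ambiguous NOE-derived
    distance restraints with r^-6 averaging, restrained simulated-annealing docking
    onto a protein domain, and NOE-consistency scoring and ranking of the resulting
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
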