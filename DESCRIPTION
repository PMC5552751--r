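Package: egresslab
Title: Ligand Egress Pathways, Path Collective Variables and Well-Tempered
    Metadynamics on Toy Molecular Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for biased molecular dynamics methodology:
    a memetic search for ligand egress pathways driven by an effective
    ligand-protein interaction functional, path collective variables s and z
    with analytic gradients, well-tempered metadynamics with adaptive
    Gaussian widths and c(t) reweighting, and conformational-state analysis
    by classical multidimensional scaling plus density-based clustering.
    Methods are exercised on built-in Langevin toy systems (analytic double
    wells and a particle cage enclosing a rigid ligand) with COLVAR/HILLS
    style text output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
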