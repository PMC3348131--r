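Package: ensemblepockets
Title: Transient Surface-Pocket Analysis over Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises transient, potentially druggable
    surface pockets that single-structure analysis misses. From one protein
    structure the package generates a native-like conformational ensemble by
    distance-constraint sampling, detects surface pockets on every conformer
    with a grid-probe method, scores their druggability (SiteScore/Dscore
    style), tracks pocket identity across the ensemble by geometric-centre
    matching, and computes per-residue pocket-lining propensities (Provar)
    written to the B-factor column for visualisation. Ships deterministic
    synthetic fixture generators (shell-with-cavity, slab, helix bundle)
    with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
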