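Package: tubewrap
Title: Helical Polymorphism of Tubular Protein Assemblies by Lattice Wrapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing helical polymorphism of tubular protein
    assemblies such as baculovirus nucleocapsids. Converts a 2D crystal
    lattice and a wrapping index (n1, n2) into a full helical symmetry
    description, builds atomic tube models for any polymorph by symmetry
    expansion of a rigid asymmetric unit, deforms tubes to elliptical
    (flattened) cross-sections at constant perimeter, renders synthetic
    density volumes, projection images and power spectra, and classifies
    segment images against a bank of polymorph references to recover
    wrapping and flattening distributions. Includes a fully seeded
    synthetic-data generator so the entire pipeline can be exercised
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
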