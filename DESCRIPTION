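Package: sanstates
Title: Conformational-State Discovery and Population Fitting from Small-Angle Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers discrete conformational states of a protein from a
    structure-prediction ensemble and quantifies their populations against
    experimental small-angle neutron scattering (SANS) data. Computes
    implicit-solvent theoretical SANS curves via a Debye sum with neutron
    contrast and optional hydration shell, filters ensemble members by
    per-model confidence (pLDDT convention), clusters theoretical curves in
    principal-component space with a silhouette-maximizing confidence
    threshold sweep, and fits experimental curves and between-condition
    difference curves with two-state linear mixtures to estimate state
    weights and the population shift. Includes structural descriptors
    (superposition RMSD, RMSF, probe-sphere pore-radius profiles,
    center-of-mass spread) and a synthetic fixture generator with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
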