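Package: rndcensus
Title: Conformational-State Census of Trimeric RND Efflux Pumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting conformational states in pseudo-C3-symmetric
    resistance-nodulation-division (RND) efflux-pump trimers from atomic
    coordinates. Extracts monomers by symmetry expansion about the estimated
    C3 axis, classifies each monomer as loose (L), tight (T), open (O) or
    closed-exit open (O*) against reference protomers using core-anchored
    Kabsch superposition and porter-domain RMSD, reconstructs the trimer
    composition distribution (LTO, TTO, TTT, ...) with bootstrap uncertainty
    and a G-test of monomer independence, estimates exit-channel bottleneck
    radii with a maximin-clearance grid search, and scores plate-dilution and
    minimum-inhibitory-concentration phenotypes. Includes a synthetic-data
    generator producing state template structures, trimer particle sets with
    known composition distributions, label tables with misclassification, and
    analytic channel fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
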