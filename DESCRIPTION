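Package: helix8
Title: Membrane-Sensitive Conformational States of Amphipathic Helices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for membrane-embedded amphipathic helices such
    as GPCR helix 8. Quantifies per-frame helicity as the fraction of intact
    i to i+4 backbone hydrogen bonds, maps conformational states as modes of a
    two-dimensional kernel density estimate over (RMSD, radius of gyration),
    and measures bilayer thickness and helix immersion depth from
    electron-density profiles along the membrane normal. Ships a synthetic
    trajectory generator (ideal helices with controlled hydrogen-bond
    breaking, Gaussian bilayer leaflets, feature-space mixtures) so every
    stage can be exercised and validated without molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
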