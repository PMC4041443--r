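Package: pisurvey
Title: Geometric Survey of DNA-Protein Pi-Interactions in Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies pi-contacts at DNA-protein interfaces in
    crystallographic coordinate files. Nucleobase-aromatic amino acid pairs
    within a 5.0 Angstrom heavy-atom cutoff are validated as genuine
    pi-pi interactions and classified by interplanar tilt (stacked,
    inclined, T-shaped) and edge role; deoxyribose-aromatic contacts are
    classified by sugar edge (single proton, bridged, face, lone pair,
    lone pair-proton) with participating-atom labels. Also prepares
    hydrogen-capped dimer models for external quantum-chemistry engines,
    implements interaction-energy bookkeeping including two-point
    complete-basis-set extrapolation and the CCSD(T) correction composite,
    generates synthetic ground-truth fixtures, and aggregates survey
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
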