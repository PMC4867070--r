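Package: azurscreen
Title: Screening for Azurin-Like Anticancer Bacteriocins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Triage pipeline for candidate anticancer bacteriocins modelled
    on the azurin/p28 system of Pseudomonas aeruginosa. Candidates are scored
    against an azurin control by the log-product of functional-annotation
    odds, filtered by a hydrophobic-percentage window anchored on azurin and
    its p28 fragment, and finally compared at the structural level by
    intersecting the p53 binding interface of each docked bacteriocin-p53
    complex with the interfaces of reference p28-azurin and azurin poses.
    Includes seeded synthetic-data generators with planted ground truth for
    every stage, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
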