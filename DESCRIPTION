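Package: ctsig
Title: Serum miRNA qPCR Array Analysis and Cross-Severity Signature Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for low-density qPCR (TaqMan) miRNA array
    threshold-cycle data: two-panel merging, per-group detection filtering
    with Ct-status classification, global mean normalization,
    comparative-Ct (2^-ddCt) relative quantitation against a calibrator
    group with explicit handling of undetected reactions, cross-group
    signature intersection with direction splits, stepwise stable
    endogenous-reference selection, hierarchical clustering of group ddCt
    profiles, and a seeded synthetic Ct-panel simulator with recovery
    scoring.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
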