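Package: solubis
Title: Critical Aggregation-Prone Regions in Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies aggregation-prone regions (APRs) in antibody variable
    domains from sequence, weighs each APR by its structure-derived local
    thermodynamic stability to flag the critical APRs that can nucleate
    aggregation from the native state, and sums the stability-corrected
    per-APR scores into a single developability score (the Solubis score).
    Includes design tools for aggregation-suppressing variants (gatekeeper
    scans over critical APRs, net-charge-increasing scans outside the
    heavy-chain CDRs), Chothia-style CDR annotation, readers for FASTA, PDB
    and per-residue free-energy tables, classifier evaluation (ROC, AUC,
    Matthews correlation) against melting/aggregation-onset temperature
    gaps, and fully synthetic test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
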