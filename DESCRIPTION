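Package: knotopt
Title: Analytics for Structure-Guided Optimization of Knottin Peptide
    Channel Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing analytics for structure-guided optimization
    campaigns of inhibitor cystine-knot (knottin) peptides targeting
    voltage-gated sodium channels such as NaV1.7.  Provides bookkeeping for
    peptide variants with non-canonical residues; fractional residue-environment
    contact statistics and polar-interaction detection from multi-model
    structural frames of peptide-channel-membrane complexes; parsing and
    two-stage ranking of design-engine scorefiles with consensus/position-weight
    matrices and design-constraint (resfile) generation; Hill-equation
    concentration-response fitting with bootstrap confidence intervals and
    subtype-selectivity fold matrices; patch-clamp excitability summaries
    (rheobase changes, remaining action-potential percentages, current-trace
    windowing and drug-sensitive subtraction); and seeded synthetic-data
    generators that emulate each of these inputs for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
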