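Package: cypselect
Title: Discovery and Selectivity Analysis for Subtype-Selective Cyclophilin Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computational pipeline for a DNA-encoded-library
    cyclophilin inhibitor campaign: error-tolerant decoding of selection
    sequencing reads and change-in-percentage-abundance enrichment analysis
    with wildcard family aggregation; chymotrypsin-coupled prolyl-isomerase
    kinetics (one-phase association fits with bleach truncation, control
    normalization, absolute IC50 with censoring); fluorescence-polarization
    saturation and competition binding models with an exact ternary
    equilibrium solver and tight-binding (Morrison) simulation; and
    panel-wide selectivity, mutant-rescue, calcium-retention-capacity and
    esterase species-fraction profiling. A synthetic-data generator emulates
    every assay input with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
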