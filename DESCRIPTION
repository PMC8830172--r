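Package: poreblock
Title: Nanopore Blockade-Event Analysis for Protein-Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-channel nanopore recordings of
    intrinsically disordered proteins such as alpha-synuclein translocating
    an alpha-hemolysin pore. Detects blockade events in current traces,
    extracts blockade amplitude and dwell time per event, fits Gaussian
    mixture population profiles and single-exponential dwell-time
    distributions, pools replicate experiments, compares conditions by
    one-way ANOVA with Student-Newman-Keuls post-hoc tests, and converts
    the comparisons into drug-binding verdicts and knot/loop binding-mode
    calls from alpha-synuclein domain-construct panels. Includes a
    ground-truthed synthetic trace generator so every stage can be
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    mclust,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
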