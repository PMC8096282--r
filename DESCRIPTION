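Package: shaperefine
Title: SHAPE-Pattern-Guided Refinement of RNA Secondary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns characteristic SHAPE (selective 2'-hydroxyl acylation
    analyzed by primer extension) reactivity patterns of RNA loop motifs
    (hairpin, bulge, internal) with paired Wilcoxon signed-rank tests, scores
    loops in predicted secondary structures with a Bayesian posterior
    log-odds penalty built on normal-inverse Gaussian and Johnson's SU
    class-conditional densities, and selects from a candidate ensemble the
    structure most consistent with those patterns. Includes parsers for
    dot-bracket, CT and SHAPE reactivity files, pseudoknot-aware loop
    extraction, structure-accuracy metrics with a noise-robustness protocol,
    a synthetic-data generator with planted reactivity patterns, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
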