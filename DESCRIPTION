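Package: wormlineage
Title: Quantitative 4D Cell-Lineage Analysis for C. elegans Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of tracked Caenorhabditis
    elegans embryonic cell lineages: reading and writing nucleus-tracking
    tables (native long format and StarryNite/AceTree nuclei exports),
    temporal and spatial embryo alignment with a Generalized Procrustes
    reference model built from control embryos, extraction of thirteen
    per-cell timing, position and division-orientation features,
    group-level statistics with a permutation-calibrated false discovery
    rate screen, and a repeated cross-validation Lasso classifier of
    embryo survival. A synthetic embryo-lineage simulator with planted
    group effects makes the whole pipeline testable end to end without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
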