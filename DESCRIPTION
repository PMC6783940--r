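Package: stemfactor
Title: Factorial Response-Surface Modeling of Pluripotent Stem Cell
    Lineage Commitment from qPCR Marker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multifactorial analysis of signaling inputs to human
    induced pluripotent stem cell (hiPSC) fate. Builds coded 3-level full
    factorial designs, converts raw qPCR cycle-threshold (Ct) tables to
    relative expression by the 2^-ddCt method, aggregates min-max normalized
    marker genes into lineage panels and weighted pluripotency/lineage
    scores, fits full quadratic response-surface models with per-term
    partial F-tests, and summarizes conditions by hierarchical clustering
    (Pearson correlation distance, average linkage) and PCA with iterative
    SVD imputation. A seeded synthetic qPCR generator emulates a 27-condition
    Wnt/FGF/TGFb factorial experiment so the full pipeline is testable
    end-to-end, including parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
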