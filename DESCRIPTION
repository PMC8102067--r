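Package: qdepth
Title: Quiescence-Depth Trajectory Analysis for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models depth of quiescence (Q-depth) in single-cell RNA-seq data.
    Cells are scored against phased cell-cycle gene signatures, the score
    matrix is embedded with a diffusion map, the three leading diffusion
    components are projected onto a two-dimensional cycle plane, and a
    principal curve fitted through the G0/G1 region yields an oriented
    per-cell quiescence depth. Also provides quality-control filtering,
    log normalization, control-bin module scoring with discrete cell-cycle
    phase assignment, derivation of treatment-response gene signatures by
    Bonferroni-corrected t-tests with a fold-change threshold, weighted
    non-negative matrix factorization for dropout imputation, and a
    negative-binomial synthetic-data generator with full ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
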