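Package: tibload
Title: Tibial Loading from Sparse-Landmark Shape Models, Beam Theory and
    Finite Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-level analysis of internal tibial loading during running.
    Reconstructs participant-specific tibia geometry from a minimal
    four-landmark set via a bounded principal-component shape model,
    quantifies reconstruction error (Jaccard index, surface error, length
    agreement), estimates muscle forces by static optimization and assembles
    the ankle joint contact force, then computes distal-third normal stress
    with a hollow-ellipse beam model and full-bone stress/strain with a
    linear-elastic tetrahedral finite element solver. Includes a synthetic
    tibia-phantom and gait-signal generator that emulates the statistical
    structure of a foot-strike-pattern running study, plus the rank-based
    statistical layer (Friedman tests with Kendall's W, exact Wilcoxon
    signed-rank post hocs with Bonferroni correction, Spearman/MAE length
    agreement, and 2D-vs-3D method-agreement summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
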