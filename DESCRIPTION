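Package: treeqsar
Title: Inverse QSAR/QSPR for Acyclic Chemical Graphs with Bounded Branch-Height
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase inverse quantitative structure activity/property
    relationship (QSAR/QSPR) modelling for hydrogen-suppressed acyclic
    chemical graphs. Phase one computes purely graph-theoretical descriptor
    vectors (split by k-internal/k-external parts of a branch-height
    decomposition) and trains a piecewise-linear (ReLU) regressor with
    cross-validation and a range-based applicability domain. Phase two
    inverts the regressor through a mixed-integer linear program that
    simultaneously certifies the existence of a chemical acyclic graph
    realising the inferred feature vector, decodes one witness graph, and
    enumerates further graphs with the same feature vector by a
    frequency-vector dynamic program. Includes synthetic-data generators and
    exhaustive small-graph oracles, SDF/JSON input and output, and
    broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    generics,
    jsonlite,
    igraph,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    optparse
Config/testthat/edition: 3
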