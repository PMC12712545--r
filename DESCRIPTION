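Package: gapscape
Title: Multi-Perspective Conservation Gap Analysis for Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale systematic conservation planning pipeline that
    scores a categorical land-use landscape for habitat quality (threat-
    weighted degradation with a half-saturation quality transform) and
    carbon storage (per-class pool densities), fits and ensembles species
    distribution models with TSS-proportional weights, summarises landscape
    fragmentation through a composite index of four patch metrics, builds an
    entropy-weighted human-disturbance cost surface, and selects candidate
    reserve networks by simulated annealing over planning units, flagging
    persistent conservation gaps across time periods. Includes a seeded
    synthetic-landscape generator so the whole pipeline is testable without
    external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
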