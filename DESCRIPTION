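Package: asterpart
Title: Partitioning Change in Mean Fitness with Aster Life-History Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying ongoing adaptation in pedigreed annual-plant
    cohorts. Fits joint exponential-family ("aster") models of sequential
    life-history components (germination, survival to flowering, pod number,
    seed number) with a sire-level random effect estimated by Laplace
    approximation, maps familial effects to mean fitness on the
    seeds-per-seed-planted scale with delta-method standard errors, and
    partitions the realized intergenerational change in mean absolute fitness
    into selection, environmental, and residual components via the Price
    equation. Includes a paternal half-sib field-design simulator for
    two-generation cohorts and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
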