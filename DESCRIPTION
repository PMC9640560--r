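Package: tpmtscreen
Title: Consensus Screening and Relative Scoring of TPMT Missense Variants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for consensus-based prioritisation of missense variants of
    human thiopurine S-methyltransferase (TPMT, UniProt P51580). Harmonises the
    heterogeneous outputs of sequence-based and structure-based effect
    predictors (labels and numeric stability scores) into canonical calls,
    applies a two-stage k-of-n vote screen with a strict strong-destabilisation
    rule for the MuSiC family, benchmarks the screen by re-detection of
    experimentally characterised deleterious variants, summarises functional
    SNP class distributions, and computes multi-category relative
    deleteriousness scores with a Total aggregate. A synthetic predictor-panel
    generator with an exact Poisson-binomial analytic oracle makes every
    pipeline stage testable without running any external predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
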