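Package: feederdefense
Title: Resource Defense and Monopolization from RFID Feeder Detections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying food-resource defense and
    monopolization in PIT-tagged nectarivore populations visiting a grid of
    instrumented feeders. Converts per-second RFID detection streams into
    visits with a gap-merge rule, computes space-use indices (daily and
    seasonal spatial concentration, spatial stability) and day- and
    feeder-level control covariates, runs permutation null models for
    concentration and feeder dominance, and fits a candidate set of linear
    mixed models with individual-specific random slopes, followed by AICc
    model selection, model averaging with unconditional standard errors,
    and extraction of per-individual defense slopes (BLUPs). Includes an
    individual-based simulator of territorial feeder visitation used for
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
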