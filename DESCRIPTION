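Package: skinpod
Title: Quantitative Skin-Sensitization Potency from Dose-Response Assay
    Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates quantitative points of departure for skin-sensitization
    risk assessment from GARDskin Dose-Response decision values. Provides
    cDV0 estimation by classifier-threshold interpolation, geometric-mean
    merging of replicate runs, construction of a composite potency scale from
    LLNA-derived NESILs and human HRIPT NOELs by Passing-Bablok
    errors-in-variables regression with orthogonal projection,
    single-parameter Huber-robust potency prediction models, and evaluation
    via absolute geometric-mean fold changes, repeated cross-validation and
    fold-change categorisation. Includes a bundled 30-chemical reference
    dataset and a synthetic-data generator for parameter-recovery studies.
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
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
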