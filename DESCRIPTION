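Package: shortform
Title: Model-Based Construction of Short-Form Health Literacy Tests
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives short forms of full-length functional health literacy
    instruments (the TOFHLA family) by exhaustive search over semantically
    grouped item sets, scored with integer-trimmed multiple linear regression
    and selected under leave-one-out cross-validation against explicit quality
    goals. Ships the canonical 67-item Danish TOFHLA item bank with its 19-set
    sentence grouping, the published 20-item short-form scoring model, the
    fixed-weight S-TOFHLA mirror models, a full psychometric validation suite
    (Cronbach's alpha, point-biserial item-scale correlations, Pearson
    correlation with confidence interval, ordinal confusion-matrix analytics),
    and a two-parameter logistic latent-trait cohort simulator for end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
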