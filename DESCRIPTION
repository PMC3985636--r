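Package: maraprog
Title: Motif Activity Inference and Regulatory Program Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers transcription-factor motif activities from promoter
    log-expression matrices and predicted binding-site counts via a
    ridge-regularized linear model (motif activity response analysis),
    decomposes the motif-activity matrix by singular value decomposition
    into independent regulatory programs, computes differential-activity
    z-statistics between experimental conditions, and selects
    representative motifs per program using significance, TF-expression
    and per-timepoint pattern filters. Includes a synthetic-study
    generator that plants known activities built from characteristic
    temporal programs so every stage can be validated by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
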