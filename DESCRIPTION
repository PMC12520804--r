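Package: mttrnascreen
Title: Mitochondrial tRNA Variant Screening and Structural Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control screening of mitochondrial tRNA variants. Maps
    rCRS coordinates onto per-gene cloverleaf secondary-structure models,
    interprets substitutions as Watson-Crick base-pair changes, scores
    evolutionary conservation from multi-species alignments, tests
    case-control association with the uncorrected Pearson chi-square, and
    classifies variants against conservation, control-frequency and
    structural criteria. Includes a synthetic cohort and alignment
    simulator so every stage of the pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
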