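Package: upkminer
Title: Literature-Based Discovery from Biomedical Abstracts via Rule-Based
    Relation Extraction and Chemical Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines undiscovered public knowledge (Swanson's ABC model) from
    MEDLINE-style abstracts. Sentences mentioning effect words are matched
    against path rules learned over link-grammar-style parse graphs to
    extract substance-effect-process-disease-body-part (SEPDB) relations;
    substance pairs are scored with a four-component similarity measure
    (semantic type, maximum-common-subgraph structural similarity, atomic
    count, XLogP); and novel hypotheses are generated by recombining
    relation contexts between similar substances and ranked by score.
    Includes a synthetic corpus generator with planted ground truth and
    precision/recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
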