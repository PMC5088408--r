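Package: nisslcyto
Title: Cytological Cell-Type Classification and Inter-Rater Reliability
    for Nissl-Stained Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic rule engine that classifies cortical cells
    (large and small neurons, astrocytes, oligodendrocytes, microglia and
    endothelial cells) from categorical cytological feature profiles of
    Nissl-stained tissue, following a four-question decision algorithm
    over nuclear staining, nuclear shape, cytoplasmic rim and the
    distribution of heterochromatin and euchromatin.  Companion tools
    compute inter-rater reliability for panels of raters applying the
    algorithm: coincidence matrices of pairwise categorizations,
    Krippendorff's alpha for nominal data with missing ratings, pairwise
    percent agreement and disagreement rankings.  A synthetic-data module
    generates labeled cytological profiles with configurable biological
    variability and simulates panels of noisy raters, reproducing the
    structure of two-test rating experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
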