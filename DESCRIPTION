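Package: wormlifespan
Title: Automated C. elegans Lifespan Assays from Plate Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to automate Caenorhabditis elegans lifespan assays from
    low-resolution daily image sequences of standard Petri plates. Implements
    a synthetic plate simulator with per-worm ground truth, extraction of
    80x80 three-day sub-image triplets centred on worm centroids, a two-stage
    cascade live/dead classifier (rule-based motion prefilter plus a
    CNN-LSTM image-sequence network trained with Adam on cross-entropy),
    dataset balancing and mixed-dataset assembly with dead-sequence
    replication, survival-curve construction with two-period monotone
    postprocessing, and per-class hit-rate and curve-error validation
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
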