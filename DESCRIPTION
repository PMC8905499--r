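Package: entityeeg
Title: Time-Resolved EEG Decoding of Individual Entities and Semantic Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying how the brain represents proper
    names and semantic categories in EEG evoked responses. Implements a
    hierarchical stimulus design (people/places, eight fine-grained
    categories, 32 individual entities plus 8 category nouns), a synthetic
    evoked-response generator with a linear forward model from entity
    vectors, standard ERP preprocessing (baseline correction, repetition
    averaging, channel standardization), confound-controlled balanced
    cross-validation splits selected by word-length Spearman correlation,
    time-resolved linear SVM classification with threshold-free cluster
    enhancement (TFCE) permutation significance, zero-shot ridge decoding
    from whole epochs to entity word vectors with leave-two-out pairwise
    evaluation, and evaluation utilities for distributional entity vectors
    (mention aggregation, similarity benchmarks, K-means clustering scored
    by the adjusted Rand index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
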