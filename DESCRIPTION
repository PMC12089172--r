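Package: camnet
Title: Analysis of Cognitive-Affective Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to represent, validate, summarize and analyze
    cognitive-affective maps (CAMs): participant-drawn belief networks whose
    concepts carry affective valences (-3 to +3 or ambivalent) and whose
    connectors carry signed strengths. Provides a canonical JSON data model,
    computer-assisted summarization of concept texts (optimal string alignment
    distance, regular-expression search, synonym dictionaries, word-vector
    cosine similarity), partition-based inter-rater reliability (pairwise
    Cohen's kappa under two category-alignment schemes, Fleiss' kappa with
    category-wise coefficients), network indicators on macro, micro and mezzo
    levels including six neighborhood-valence variants, cross-CAM aggregation
    via canonical adjacency matrices, concept co-occurrence phi coefficients,
    valence-profile hierarchical clustering, CAM slicing with component
    validation, a replayable analysis protocol, a synthetic CAM generator for
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
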