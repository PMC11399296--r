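Package: radrec
Title: Recommender-Based Bone Tumour Classification from Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based retrieval and classification of bone tumour
    radiographs. Crops a region of interest from a grayscale radiograph,
    embeds it with a deterministic reference descriptor (or any pluggable
    extractor), indexes training embeddings with random-hyperplane
    locality-sensitive hashing, retrieves the k nearest previously
    diagnosed cases by hamming distance, classifies the query by majority
    vote over the retrieved cases, and evaluates with precision-at-k and
    macro classification metrics. Ships a synthetic cohort, image and
    embedding generator emulating a ten-entity bone tumour cohort with
    strong class imbalance and per-entity multimodal appearance, so the
    whole pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
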