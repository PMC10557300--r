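Package: latentneeds
Title: Z-Score Morpheme Selection for Mining Latent Needs from Interview Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for extracting latent needs of patients
    and caregivers from transcribed interview records. Flags candidate records
    with an expectation-adverb marker lexicon, tokenizes Japanese text into
    morphemes (pluggable backend with a fixture tokenizer for testing), selects
    class-discriminative morphemes by the absolute difference of per-class
    Z-scores of occurrence counts, vectorizes records with TF-IDF, balances
    classes by random undersampling, and compares multinomial Naive Bayes,
    linear-kernel SVM, and random-forest classifiers with confusion-matrix
    metrics, with and without the selection step. Includes a synthetic corpus
    generator with planted discriminative vocabulary for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    dplyr,
    purrr,
    readr,
    stringr,
    stringi,
    jsonlite,
    rlang,
    withr,
    Matrix,
    e1071,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
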