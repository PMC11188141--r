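Package: gestaltR
Title: Classifier-Encoder Embeddings and Ancestry-Stratified Gallery
    Matching for Facial Phenotype Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the classifier-as-encoder paradigm for
    next-generation phenotyping at desk scale: a softmax classifier is
    trained on the frequent disorders of a cohort, its penultimate layer
    is used as an embedding encoder, and test images are matched against
    a gallery of embeddings with known diagnoses by cosine distance.
    Includes a synthetic cohort simulator with long-tailed disorder
    sizes, continental ancestry structure and an ancestry-by-disorder
    interaction in feature space; stratified top-k accuracy evaluation;
    ancestry-composition experiments for the training set and the
    gallery set; and HPO-defined symptom-group assignment with
    co-occurrence summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
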