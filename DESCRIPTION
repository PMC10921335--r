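Package: topicrisk
Title: Topic-Enhanced Embeddings and Review-Augmented Clustering for
    Mining Risk Factors from Short Health Comments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for mining disease risk factors from
    short social-media comments. Provides text cleaning, dictionary-aware
    segmentation and vocabulary construction; a semi-automated weighted
    topic dictionary built by embedding-neighbour expansion from seed
    phrases; a topic-enhanced Skip-gram word embedding trained with a
    joint context-plus-topic loss; a convolutional (TextCNN) binary
    classifier for risk-factor comments with stratified cross-validation;
    single-pass incremental clustering with an automatic singleton review
    pass and a manual-review report; TextRank keyword extraction per
    category; and a seeded synthetic-corpus generator with planted topics
    so the whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
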