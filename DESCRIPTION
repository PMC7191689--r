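Package: stsfuse
Title: Gated Fusion of Handcrafted and Neural Sentence-Pair Representations for Clinical Semantic Textual Similarity
Version: 0.1.0
Authors@R: person("STS", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores the semantic similarity of clinical sentence pairs on the
    0-5 scale used by clinical semantic textual similarity (STS) benchmarks.
    Sentence pairs are represented two ways: a handcrafted feature vector
    (lengths, inverse document frequency, n-gram overlap, and kernel
    similarities over averaged word embeddings) and a dense vector from one of
    three trainable pair encoders (Siamese convolutional, Siamese
    bidirectional LSTM, or a transformer over the concatenated pair). The two
    representations are projected into a common space and blended component-wise
    by a learned sigmoid gate feeding a bounded regression head. Includes
    corpus input/output with stratified splitting, clinical-style text
    normalization, a synthetic scored-pair generator, per-score-interval
    evaluation (Pearson and mean squared error), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
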