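Package: protlm
Title: Desk-Scale Protein Language Modeling and Sequence Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for training and evaluating small autoregressive
    (causal) protein language models. Provides byte-pair-encoding
    tokenization of amino-acid sequences, a decoder-only transformer
    trained by negative log-likelihood with Adam, a decoding suite
    (greedy, beam search, temperature/top-k/nucleus sampling with
    repetition penalty), calibration of sampling parameters by matching
    amino-acid propensities against a natural reference, HSSP
    twilight-zone classification of homology-search hits, sequence
    similarity networks, and Markov-grammar corpus simulators with
    known entropy rates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
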