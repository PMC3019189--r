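Package: linhmm
Title: Linear-Memory Parameter Training for Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training the parameters of hidden Markov models with
    memory requirements that are independent of the sequence length. Implements
    one-pass, linear-memory algorithms for Viterbi training and stochastic
    expectation-maximization (EM) training that propagate cumulative
    transition and emission counts alongside the dynamic-programming values,
    together with the classical two-step procedures (Viterbi decoding with
    traceback, forward algorithm with stochastic back-tracing) and a
    Baum-Welch baseline with both forward-backward and one-pass expected-count
    engines. Ships example models (the dishonest casino, an extended casino
    with run-length structure, and a CpG-island model), a generative simulator
    with exact fixed-length sampling, parameter tying with pseudo-count
    updates, and a cross-validation harness that scores per-position
    prediction accuracy and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
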