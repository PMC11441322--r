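Package: kgrag
Title: Token-Optimized Knowledge-Graph Retrieval-Augmented Generation for
    Biomedical Question Answering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieval-augmented generation over SPOKE-style biomedical
    property graphs. Links disease mentions in free-text questions to graph
    nodes by sentence-embedding similarity, retrieves quality-filtered
    one-hop neighborhoods, verbalizes attributed triples into English
    context sentences (optionally with provenance and statistical
    evidence), prunes context by a percentile-plus-floor semantic
    similarity rule under a context-volume budget, and assembles enriched
    prompts for pluggable chat-model backends. Ships deterministic mock
    backends and embedders, a synthetic graph and question-set generator,
    and a benchmark harness with bootstrap accuracy, Jaccard retrieval
    scoring, lowercase-perturbation robustness, and token-usage reports.
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
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
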