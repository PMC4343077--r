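Package: phenorec
Title: Phenotype Concept Recognition, Evaluation and Test Suites for the
    Human Phenotype Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes Human Phenotype Ontology (HPO) style concepts in
    free text with character-exact span boundaries.  Matching is
    dictionary-based over an ontology-derived lexicon and supports
    order-invariant token signatures, decomposition of coordinated
    phenotype mentions into their atomic concepts, and optional handling
    of non-canonical (verbal) phenotype expressions.  The package also
    reads and writes standoff annotation corpora, scores any annotator
    against a gold standard with exact-boundary precision, recall and
    F-score stratified by top-level phenotype category, and generates
    stratified lexical test suites (label length, punctuation, numerals,
    stop words, inflection, token reordering, synonyms, coordination)
    for standardized error analysis of concept recognizers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
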