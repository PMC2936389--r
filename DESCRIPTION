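Package: hedgedev
Title: Empirical Development and Evaluation of Literature Search Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the empirical development and testing of search
    filters ("hedges") for bibliographic databases such as PubMed/Medline.
    Reads and writes MEDLINE tagged-format records and PMID lists; mines
    candidate free-text terms by differential document prevalence between a
    development set of known-relevant references and a random population
    sample; represents, parses and executes PubMed-style Boolean search
    strategies with [tiab] and [mh] field tags (including MeSH subheadings
    and optional tree explosion) against a local corpus; evaluates
    strategies by sensitivity, precision and number needed to read; and
    estimates the total number of relevant references in a database from a
    screened random sample of a joint retrieval.  A seeded synthetic-corpus
    generator with controlled per-term prevalences makes the whole pipeline
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
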