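Package: swenegex
Title: Rule-Based Negation Detection for Swedish Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects negated clinical findings in Swedish free text using a
    NegEx-style trigger-phrase algorithm: categorised negation cues (pre-,
    post-, pseudo-negations and scope-terminating conjunctions), a bounded
    word-distance scope window, longest-match trigger lookup, and Swedish
    disambiguation rules for the ambiguous cues "utan" and "icke".  Includes
    morphological expansion of trigger lexicons (negative-quantifier gender
    and number forms, adjective and verb inflection, subordinate-clause word
    order inversion), preprocessing and compound-aware matching of ICD-10
    style term lists, an evaluation harness with confidence intervals,
    inter-rater agreement statistics and a chi-squared two-proportion test,
    and a seeded synthetic corpus generator for end-to-end testing without
    access to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
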