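Package: edssnlp
Title: Rule-Based and Neural Extraction of EDSS Scores from Multiple
    Sclerosis Clinic Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts and predicts the Expanded Disability Status Scale
    (EDSS) total score and the eight functional-system subscores from
    free-text multiple-sclerosis clinic notes.  Provides a rule-based
    extractor (keyword/number co-occurrence at first mention, plus
    finding-pattern/severity-adjective rules for subscores), skip-gram
    word embeddings trained on the note corpus, a convolutional text
    classifier over those embeddings, and a cascade that falls back to
    the classifier only when no explicit score is written.  Ships the
    full evaluation protocol (exact and tolerance accuracy, macro
    precision/recall/F1, converted accuracy, unknown-prediction rate,
    Pitman permutation tests, leakage-free patient-level splitting) and
    a seeded synthetic clinic-note generator so the whole pipeline is
    testable without access to protected health records.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
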