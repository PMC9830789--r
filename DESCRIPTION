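Package: negdetect
Title: Negation Detection in Clinical Free Text
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Detects negation of annotated medical terms in clinical free
    text. Implements a ConText-style trigger/scope rule engine with
    pseudo-trigger precedence and termination triggers, a bidirectional
    recurrent context classifier with entity-placeholder abstraction, a
    byte-pair-encoding subword tokenizer and continuous-bag-of-words
    embedding trainer, entity-centered token windows for transformer-style
    scorers, a majority-voting ensemble, shared-fold cross-validation with
    per-category precision/recall/F1, an error taxonomy with Cohen's kappa
    agreement, and a synthetic clinical-corpus generator with known ground
    truth so every component is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
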