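# negdetect

Negation detection for annotated medical terms in clinical free text.

Clinical notes assert absence as often as presence: "no signs of
infection" must not be extracted as *infection*. Given documents with
standoff entity annotations (character spans of medical terms),
`negdetect` classifies each entity as **negated** or **not negated**
with three method families behind one prediction contract, and ships
the harness to compare them honestly:

* a **ConText-style rule engine** — trigger lexicon (forward/backward
  negation, pseudo- and termination triggers), pseudo-trigger
  precedence, longest-match resolution, directional scopes bounded by
  the sentence or a termination trigger;
* a **bidirectional LSTM context classifier** over
  placeholder-abstracted token windows (15 left / 10 right), with a
  from-scratch BPE subword tokenizer and an optional CBOW embedding
  pretrainer — forward pass and backprop written in base R;
* a **transformer adapter** — entity-centered token windows under a
  512-token limit, validation windows centered on exactly one entity,
  and max/mean subword-to-word score aggregation — for any external
  scorer (a finetuned model, or a mock in tests);
* a **majority-voting ensemble** of exactly three classifiers;
* an **evaluation harness**: shared 10-fold cross-validation,
  precision/recall/F1 for the negated class per record category
  (undefined ratios reported as absent, never 0), error records with a
  ten-category taxonomy, error-set intersection counts, Cohen's kappa;
* a **synthetic corpus generator** with known ground truth (trigger
  grammar, four record categories with realistic length statistics,
  14% negated prevalence, minus/whitespace/punctuation noise), so every
  component is testable without restricted clinical data.

For the negated class with `tp`, `fp`, `fn` counted per entity:

    precision = tp / (tp + fp)
    recall    = tp / (tp + fn)
    F1        = 2 * precision * recall / (precision + recall)

and an entity is negated under the rule engine iff one of its tokens
falls in the scope of a negation trigger, where the default scope is
the remainder of the sentence in the trigger's direction, truncated at
the nearest termination trigger.

## Worked example

```r
library(negdetect)

lex <- compile_lexicon(list(
  trigger_entry("no signs of", "negation_forward"),
  trigger_entry("but", "termination")))

text <- "No signs of infection, but pneumonia persists"
doc <- annotated_document("d1", text, "radiology_report", list(
  entity_annotation(12, 21, "infection"),
  entity_annotation(27, 36, "pneumonia")))

classify_entities_rule(doc, lex)
#>   doc_id entity_index       label probability method
#> 1     d1            1     negated          NA   rule
#> 2     d1            2 not_negated          NA   rule
```

"infection" is negated; the termination trigger "but" cuts the scope
before "pneumonia". End-to-end on synthetic data with known truth:

```r
gen   <- generate_corpus(generator_config(n_documents = 300, seed = 7))
preds <- annotate_corpus_rule(gen$corpus)          # packaged Dutch lexicon
compute_metrics(preds, corpus_entities(gen$corpus),
                stratify_by_category = FALSE)
#>   stratum  tp fp fn  tn precision recall f1
#> 1     all 112  0  0 669         1      1  1
```

Perfect scores are expected here *by construction* — the generator's
trigger grammar is aligned with the packaged lexicon and the corpus is
noise-free; see the methods vignette for what that does and does not
establish. Add noise and the documented failure modes appear (e.g.
`minus_rate = 1` turns every trigger negation into the clinical
"term-" shorthand, which a lexicon without a hyphen rule misses).

The same pipeline as a command line:

```sh
Rscript inst/cli/negdetect generate-synthetic --output corpus.jsonl \
        --n-documents 80 --seed 5
Rscript inst/cli/negdetect annotate --input corpus.jsonl --output preds.jsonl
Rscript inst/cli/negdetect evaluate --predictions preds.jsonl \
        --gold corpus.jsonl --output metrics.csv
```

Subcommands: `annotate`, `train-bilstm`, `predict`, `ensemble`,
`evaluate`, `error-report`, `generate-synthetic`.

## Acceptance

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The acceptance-target list for this package is empty — the original
study's headline numbers were computed on a request-only clinical
corpus — so the script runs an end-to-end smoke check and writes an
empty JSON object. The substantive acceptance criteria (worked
examples, monotonicity properties, brute-force oracle equivalence,
parameter recovery of the neural classifier, metric/kappa/fold
identities, prevalence calibration) are
`tests/testthat/test-acceptance.R`, one test per criterion.
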