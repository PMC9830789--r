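---
title: "Methods: negation detection for annotated clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: negation detection for annotated clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical free text mentions findings, symptoms and diagnoses that are
frequently *absent*: "no signs of infection" asserts the opposite of
"infection". Any label-extraction pipeline that feeds clinical
prediction models therefore needs, for each annotated medical term, a
binary decision: **negated** or **not negated**. `negdetect` implements
three method families behind one prediction contract, an ensemble, an
evaluation harness, and a synthetic corpus generator so that all of it
is testable without access to restricted clinical data.

Entities are taken as given (character spans into the document text);
named-entity recognition is out of scope. Character offsets are 0-based
and half-open throughout, the dominant standoff-annotation convention.
Input text is taken verbatim — no unicode normalization — because
offset integrity trumps normalization.

## The rule engine

The engine is a ConText-style trigger/scope algorithm:

* **Negation triggers** open a scope, *forward* ("geen ...", "no
  evidence of ...") or *backward* ("... uitgesloten", "... was ruled
  out"). The default scope is the remainder of the sentence in the
  trigger's direction; an optional `max_scope` limits it to a number of
  words instead.
* **Pseudo-triggers** are phrases containing a negation trigger that
  must not fire ("niet alleen" / "not only"). Any negation match fully
  contained in a pseudo match is discarded before anything else
  happens.
* **Termination triggers** ("maar" / "but") cut a scope short: the
  scope ends just before the nearest termination match in the scope
  direction.

An entity is negated iff at least one of its tokens lies in at least
one negation scope (logical OR over scopes — the combination semantics
are not fixed by the literature, so the least surprising choice was
made once). An entity overlapping the trigger's own match is never
negated by that trigger: a lexicon phrase like "geen eetlust" must not
negate an entity annotation sitting on "eetlust" inside it.

Matching is case-insensitive everywhere; mixed-case trigger spellings
are a documented error source for learned models and are free for a
rule engine to get right. Among overlapping candidate matches the
longest pattern wins ("no evidence of" beats "no").

Sentence splitting is deliberately an injection point: the default is a
rule-based splitter (sentence-final `.`, `!`, `?` and newlines) because
a parser-based splitter is a replaceable dependency, and any function
returning sentence spans with token spans can be plugged in. Tokens are
maximal alphanumeric runs plus single punctuation marks; a *trailing*
hyphen stays attached to its word, because the clinical minus shorthand
("koorts-" = no fever) must survive tokenization to be diagnosable. A
preprocessing flag (`split_minus`) detaches it instead.

If an entity ever spans a sentence boundary (possible under bad
splitting), it is assigned to the sentence containing its first token —
a flagged convention, not a claim of correctness.

The packaged Dutch lexicon is **illustrative**: the original study's
exact trigger list is unpublished, so the TSV shipped under
`inst/extdata/` covers the trigger categories without claiming to
reproduce anyone's rule set.

## The recurrent classifier

The neural route classifies the *context* of an entity, not the entity
itself:

1. **Placeholder abstraction** — the entity tokens are replaced by one
   reserved symbol, so "no signs of diabetes mellitus" and "no signs of
   bronchitis" become the same training example. The model learns the
   negation pattern once.
2. **Asymmetric window** — 15 word tokens to the left and 10 to the
   right of the entity, clipped at document edges. The window is
   counted in *word* tokens before subword encoding, so its semantics
   do not depend on the subword vocabulary size (whether the original
   counted word or subword tokens is unstated; this choice is flagged
   for anyone comparing against other implementations).
3. **BPE subword tokenizer** — trained from the corpus characters up,
   merging the most frequent adjacent pair until the vocabulary budget
   is reached; frequency ties break lexicographically so training is
   deterministic. Whitespace is never merged, which makes
   detokenization exact concatenation.
4. **Optional CBOW embeddings** — a plain continuous-bag-of-words
   trainer (predict the center token from averaged context vectors,
   full softmax, SGD) can pre-train the embedding table on any domain
   text supplied to it.
5. **biLSTM + fully-connected head** — one LSTM layer per direction,
   final states concatenated, one hidden dense layer, sigmoid output,
   (optionally class-weighted) cross-entropy, Adam. The forward pass
   and backpropagation-through-time are written out in base R with BLAS
   matrix products; no deep-learning runtime is required.

Reference defaults are embedding 300, hidden 128 per direction, one
dense layer of 64 — the original toolkit's exact settings are not
enumerated anywhere, so these are this package's own defaults, all
exposed in `hyperparams`. The decision threshold is 0.5 with `>=`
mapping to *negated*. Out-of-vocabulary tokens map to a reserved
unknown id and never raise. Class weighting (off by default) counters
the ~14% prevalence of the negated class with inverse-frequency
weights.

## The transformer adapter

Fine-tuning an actual pretrained transformer needs external weights and
significant hardware, so the transformer itself sits behind a scorer
interface: anything that maps a token window to per-subword-token
probabilities. The package owns the plumbing that is testable at desk
scale:

* **Entity-centered windows** under a maximum sequence length (default
  512): the left side gets `floor(limit/2)` tokens — the off-by-one
  convention had to be fixed somewhere — clipped at document edges with
  the surplus given to the other side. Training windows may overlap; in
  validation mode each entity is the center of exactly one window and
  only center entities are scored, so no entity is evaluated from a
  truncated context.
* **Subword-to-word aggregation**: subword tokenization makes negation
  estimates vary across the tokens of one word, so the per-word score
  is the maximum (default, the more sensitive choice) or mean of the
  aligned token probabilities.

Entities in records longer than the limit cannot be scored by a
limited method; `overlength_entities()` exposes this as a per-method
capability mask rather than a corpus filter, leaving the drop-or-keep
decision to the caller.

## Ensemble and evaluation

The ensemble is a majority vote over exactly three hard labels per
entity — whether the original combined hard labels or probabilities is
unstated, and the vote is *defined* over labels, so hard labels it is.
Evaluation uses k-fold cross-validation (default 10) with the same
folds served to every method. Fold grouping defaults to record-level so
no document text leaks between train and test folds (the study does
not state its grouping; entity-level grouping is available as config).
Predictions are pooled over test folds and metrics computed once
(micro), matching the convention of reporting one number per record
category; per-fold metrics are kept because fold-to-fold variance is
itself informative.

Precision, recall and F1 are computed for the *negated* class.
Undefined ratios (zero denominators) are reported as absent (`NA`),
never as 0 — silently zeroing them deflates averages.

Error analysis: every false positive and false negative becomes an
error record; a ten-category taxonomy (uncommon negation, minus, scope,
punctuation, negation of a different term, wrong modality, speculation,
ambiguity, other, annotation error) is *validated and tabulated* but
never auto-assigned — category judgments are human work. Agreement on
shared errors is quantified with Cohen's kappa
(`(p_o - p_e) / (1 - p_e)`, `NA` when `p_e = 1`). Error-set overlap
between methods is reported as exclusive intersection counts that sum
to the union of the error sets.

## The synthetic generator

The generator emulates the *statistics* of a clinical corpus, not
medicine: invented term-like strings (packaged, no patient-derived
text), a small set of Dutch function words, and a trigger grammar
aligned with the packaged lexicon. Stated-world defaults:

* four record categories mixed by their corpus share;
* per-category mean sentences and words per record of
  (2.1, 17.8), (3.8, 30.0), (3.6, 19.1), (4.1, 33.8) for GP entries,
  specialist letters, radiology reports and discharge letters, with
  negative-binomial lengths because real record lengths are
  over-dispersed;
* 14% negated-entity prevalence, each entity an independent draw;
* noise rates (all 0 by default): minus shorthand, whitespace deletion,
  abbreviation periods — the three textual phenomena that dominate
  realistic error analyses.

Negations are realized only through the grammar (forward/backward
triggers in scope, termination triggers between mixed-label pairs,
occasional pseudo-triggers in non-negated sentences), and every
generated sentence with triggers is re-checked at generation time
against a literal token-level scope oracle — the generator refuses to
emit a document whose labels its own semantics cannot certify. Noise
injection rewrites the token-level structure (so offsets are
recomputed, never patched) and updates the per-entity traces; it
therefore requires a corpus that still carries its generation
structure.

What a green test does establish: the engine implements the scope
semantics exactly (it scores 1.0 on noise-free output by construction),
and the learned classifier can recover a trigger grammar from ~2000
examples. What it does not establish: performance on real clinical
text, whose negation vocabulary is open-ended, whose sentences are not
generated by any grammar, and whose annotations disagree with
themselves at a measurable rate.

## Numerical and testing choices

* All randomness (generator, fold shuffling, network init, batch order)
  flows from explicit integer seeds; identical config + seed gives
  byte-identical corpora and identical predictions.
* BPE pair-frequency ties break lexicographically; Adam is run with
  the conventional (0.9, 0.999, 1e-8) constants; gradients are clipped
  to a global norm of 5 (without clipping, backpropagation through
  time visibly destabilizes mid-training on some seeds); sigmoid
  outputs are clamped away from 0/1 only inside the loss.
* The acceptance check for the classifier (held-out F1 at least 0.9 on
  2000 synthetic entities, averaged over three fixed seeds) runs with a
  reduced network (embedding 48, hidden 32) purely to fit a
  single-CPU test budget; the data size, split and seeds are the
  stated world, the width is not.
* The worked acceptance examples and all property tests (pseudo and
  termination monotonicity, brute-force oracle equivalence on short
  sentences, fold arithmetic, F1 betweenness, kappa symmetry, window
  invariants, prevalence calibration) live in
  `tests/testthat/test-acceptance.R`.

## Known limitations

* The packaged lexicon is illustrative, not a reproduction of any
  published rule set, and is small.
* The CBOW trainer uses a full softmax — fine for the vocabulary sizes
  the package targets, wrong tool for a million-type corpus.
* The pure-R biLSTM is CPU-bound; it trains thousands, not millions,
  of examples in reasonable time.
* The generator's "Dutch" is function-word soup around invented terms;
  it exercises code paths, and nothing about it should be mistaken for
  clinical language.
* Temporality and experiencer context dimensions, probability
  calibration, and significance testing between methods are
  deliberately out of scope.
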