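# Entity-centered token windows under a maximum sequence length, the
# validation rule that only center entities count, and subword-to-word
# probability aggregation. The transformer itself stays behind a scorer
# interface: anything mapping a token window to per-token probabilities
# (a finetuned masked language model, or a mock in tests) plugs in.

#' Maximum sequence length
#'
#' @param max_sequence_length Positive integer; default 512, the usual
#'   transformer limit that forces windowing of long records.
#' @return A `sequence_limit`.
#' @export
sequence_limit <- function(max_sequence_length = 512L) {
  max_sequence_length <- as.integer(max_sequence_length)
  if (is.na(max_sequence_length) || max_sequence_length < 1L)
    stop("sequence_limit: must be positive")
  structure(list(max_sequence_length = max_sequence_length),
            class = "sequence_limit")
}

#' Build entity-centered token windows
#'
#' Each window is centered on its entity: the left side gets
#' `floor(limit/2)` tokens, clipped at the document edges with the
#' surplus given to the other side, and no window ever exceeds the
#' limit. In training mode windows may overlap (an entity can occur in
#' several windows); in validation mode each entity is the center of
#' exactly one window and only that center entity is scored from it.
#'
#' @param doc_tokens Character vector of document tokens (or an integer
#'   document length).
#' @param entities List of 1-based inclusive token ranges `c(from, to)`,
#'   one per entity.
#' @param limit A [sequence_limit()].
#' @param mode `"validation"` or `"training"`.
#' @return List of `token_window`s: `list(from, to, center_entity, mode)`
#'   with 1-based inclusive token ranges.
#' @export
build_token_windows <- function(doc_tokens, entities,
                                limit = sequence_limit(),
                                mode = c("validation", "training")) {
  mode <- match.arg(mode)
  n <- if (is.character(doc_tokens)) length(doc_tokens)
       else as.integer(doc_tokens)
  L <- limit$max_sequence_length
  lapply(seq_along(entities), function(k) {
    rng <- entities[[k]]
    from_e <- rng[1]; to_e <- rng[length(rng)]
    if (from_e < 1L || to_e > n || from_e > to_e)
      stop("build_token_windows: validation error: entity ", k,
           " range [", from_e, ", ", to_e, "] outside 1..", n)
    if (n <= L) {
      from <- 1L; to <- n
    } else {
      center <- from_e
      from <- center - L %/% 2L
      to <- from + L - 1L
      if (from < 1L) { from <- 1L; to <- L }
      if (to > n) { to <- n; from <- n - L + 1L }
    }
    structure(list(from = from, to = to, center_entity = k, mode = mode,
                   entity_range = c(from_e, to_e)),
              class = "token_window")
  })
}

#' Aggregate subword token scores into one word score
#'
#' Subword tokenization makes the negation estimate vary over the tokens
#' of a single word; the per-word score is taken as the maximum (default,
#' the more sensitive choice) or the mean of the aligned token
#' probabilities.
#'
#' @param scores A `token_score_vector`: `list(probs, word_index)` with
#'   per-subword probabilities in `[0, 1]` and a parallel integer vector
#'   aligning each subword token to its word.
#' @param word Word index to aggregate.
#' @param mode `"max"` or `"mean"`.
#' @return A single probability.
#' @export
aggregate_word_score <- function(scores, word, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(scores$probs) == length(scores$word_index))
  if (any(scores$probs < 0 | scores$probs > 1))
    stop("aggregate_word_score: probabilities outside [0, 1]")
  p <- scores$probs[scores$word_index == word]
  if (!length(p))
    stop("aggregate_word_score: alignment error: no tokens aligned to word ",
         word)
  if (mode == "max") max(p) else mean(p)
}

#' Score token windows with an external scorer
#'
#' Runs a scorer over each window and turns the aggregated score of the
#' window's *center* entity into a hard prediction at threshold 0.5
#' (`>=` is negated). The scorer interface: a function taking a
#' `token_window` and returning a `token_score_vector` whose
#' `word_index` aligns subword tokens to *document* token indices.
#' Scorer failures propagate with the window identity attached.
#'
#' @param scorer `function(window) -> token_score_vector`.
#' @param windows List of `token_window`s (validation mode: one per
#'   entity).
#' @param mode Aggregation over the entity's subword tokens, `"max"`
#'   (default) or `"mean"`.
#' @param threshold Decision threshold (default 0.5).
#' @param doc_id Optional document id stamped on the predictions.
#' @return Prediction data frame with `method = "transformer"`.
#' @export
score_with_adapter <- function(scorer, windows, mode = c("max", "mean"),
                               threshold = 0.5, doc_id = NA_character_) {
  mode <- match.arg(mode)
  rows <- lapply(windows, function(w) {
    scores <- tryCatch(scorer(w), error = function(e)
      stop("score_with_adapter: scorer failed on window [", w$from, ", ",
           w$to, "] (center entity ", w$center_entity, "): ",
           conditionMessage(e), call. = FALSE))
    words <- w$entity_range[1]:w$entity_range[2]
    p <- max(vapply(words, function(wd)
      aggregate_word_score(scores, wd, mode), numeric(1)))
    data.frame(doc_id = doc_id, entity_index = w$center_entity,
               label = if (p >= threshold) "negated" else "not_negated",
               probability = p, method = "transformer",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mock scorers for the adapter
#'
#' Stand-ins for an external pretrained scorer, used in tests and demos:
#' `constant_scorer(p)` emits `p` on every token;
#' `lexical_mock_scorer(doc_tokens, trigger)` emits 1.0 on every token
#' that follows the literal trigger word (case-insensitive) with no
#' sentence-final period in between, 0 elsewhere — i.e. it mimics a
#' forward sentence scope, enough to agree with the rule engine on
#' single-trigger synthetic sentences.
#'
#' @param p Constant probability.
#' @return A scorer function for [score_with_adapter()].
#' @export
constant_scorer <- function(p) {
  force(p)
  function(window) {
    idx <- window$from:window$to
    list(probs = rep(p, length(idx)), word_index = idx)
  }
}

#' @rdname constant_scorer
#' @param doc_tokens Document word tokens the windows index into.
#' @param trigger Literal trigger word.
#' @export
lexical_mock_scorer <- function(doc_tokens, trigger = "geen") {
  force(doc_tokens); force(trigger)
  function(window) {
    idx <- window$from:window$to
    toks <- tolower(doc_tokens[idx])
    probs <- numeric(length(idx))
    open <- FALSE
    for (i in seq_along(idx)) {
      if (toks[i] == tolower(trigger)) { open <- TRUE; next }
      if (grepl("^[.!?]+$", toks[i])) { open <- FALSE; next }
      if (open) probs[i] <- 1
    }
    list(probs = probs, word_index = idx)
  }
}
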