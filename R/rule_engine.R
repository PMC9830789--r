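# ConText-style rule engine: trigger lexicon, matching with pseudo-trigger
# precedence, directional scopes bounded by sentence or termination
# triggers, and entity labeling.

TRIGGER_CATEGORIES <- c("negation_forward", "negation_backward",
                        "pseudo", "termination")

#' Create a trigger lexicon entry
#'
#' @param pattern Literal phrase or regular expression (matched
#'   case-insensitively). Plain phrases (letters/digits/spaces only) are
#'   matched at word boundaries; anything else is treated as a raw regex.
#' @param category One of `negation_forward`, `negation_backward`
#'   (direction of the scope the trigger opens), `pseudo` (a phrase
#'   containing a negation trigger that must *not* fire, e.g. "not only"),
#'   or `termination` (cuts a negation scope short, e.g. "but").
#' @param max_scope Optional positive word count limiting the scope;
#'   absent means the default scope, the remainder of the sentence.
#'   Only meaningful for the negation categories.
#' @return A `trigger_entry`.
#' @export
trigger_entry <- function(pattern,
                          category = c("negation_forward", "negation_backward",
                                       "pseudo", "termination"),
                          max_scope = NULL) {
  category <- match.arg(category)
  if (!nzchar(pattern)) stop("trigger_entry: empty pattern")
  if (!is.null(max_scope)) {
    max_scope <- as.integer(max_scope)
    if (is.na(max_scope) || max_scope < 1L)
      stop("trigger_entry: max_scope must be >= 1 (pattern '", pattern, "')")
    if (!category %in% c("negation_forward", "negation_backward"))
      stop("trigger_entry: max_scope only applies to negation categories ",
           "(pattern '", pattern, "')")
  }
  structure(list(pattern = pattern, category = category,
                 max_scope = max_scope), class = "trigger_entry")
}

wrap_pattern <- function(pattern) {
  if (grepl("^[\\p{L}\\p{N} ]+$", pattern, perl = TRUE))
    paste0("(?<![\\p{L}\\p{N}])(?:", pattern, ")(?![\\p{L}\\p{N}])")
  else paste0("(?:", pattern, ")")
}

#' Compile a trigger lexicon
#'
#' Validates and compiles entries into a matchable lexicon. Matching is
#' case-insensitive; among overlapping candidate matches the longest
#' pattern wins. Invalid regexes are rejected naming the offending
#' pattern, as are duplicate (pattern, category) pairs.
#'
#' @param entries Non-empty list of [trigger_entry()] objects.
#' @return A `trigger_lexicon`.
#' @export
compile_lexicon <- function(entries) {
  if (length(entries) == 0L)
    stop("compile_lexicon: configuration error: empty entry list")
  entries <- lapply(entries, function(e) {
    if (inherits(e, "trigger_entry")) e
    else do.call(trigger_entry, e)
  })
  pats <- vapply(entries, `[[`, character(1), "pattern")
  cats <- vapply(entries, `[[`, character(1), "category")
  dup <- duplicated(paste(tolower(pats), cats, sep = "\r"))
  if (any(dup))
    stop("compile_lexicon: duplicate entry for pattern '",
         pats[which(dup)[1]], "' (", cats[which(dup)[1]], ")")
  wrapped <- vapply(pats, wrap_pattern, character(1), USE.NAMES = FALSE)
  for (i in seq_along(wrapped)) {
    ok <- tryCatch({ grepl(wrapped[i], "", perl = TRUE); TRUE },
                   condition = function(c) FALSE)
    if (!ok)
      stop("compile_lexicon: pattern '", pats[i], "' does not compile")
  }
  structure(list(
    pattern = pats, category = cats, regex = wrapped,
    max_scope = vapply(entries, function(e)
      if (is.null(e$max_scope)) NA_integer_ else e$max_scope, integer(1))),
    class = "trigger_lexicon")
}

#' @export
print.trigger_lexicon <- function(x, ...) {
  cat("<trigger_lexicon> ", length(x$pattern), " entries (",
      paste(sprintf("%s: %d", names(table(x$category)), table(x$category)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read a trigger lexicon from a TSV file
#'
#' UTF-8 tab-separated file with columns `pattern`, `category`,
#' `max_scope` (empty = default sentence scope); `#` starts a comment
#' line. The scope direction is folded into the category
#' (`negation_forward` / `negation_backward`).
#'
#' @param path TSV file.
#' @return A compiled `trigger_lexicon`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  entries <- lapply(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("read_lexicon: bad line '", line, "'")
    trigger_entry(f[1], f[2],
                  max_scope = if (length(f) >= 3L && nzchar(trimws(f[3])))
                    as.integer(f[3]) else NULL)
  })
  compile_lexicon(entries)
}

#' The packaged default Dutch trigger lexicon
#'
#' An illustrative ConText-style Dutch lexicon shipped with the package
#' (the original study's exact trigger list is not published). Also the
#' default trigger grammar of the synthetic generator.
#'
#' @return A compiled `trigger_lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon_nl.tsv",
                           package = "negdetect", mustWork = TRUE))
}

#' Find trigger matches in one sentence
#'
#' Matches every lexicon entry case-insensitively inside the sentence.
#' Two precedence rules apply: any negation-trigger match whose span is
#' fully contained in a pseudo-trigger match is removed (pseudo-triggers
#' take precedence), and among remaining overlapping candidates the
#' longest match wins.
#'
#' @param sentence A sentence span from [split_sentences()].
#' @param text The document text the sentence was split from.
#' @param lexicon A compiled `trigger_lexicon`.
#' @return Data frame of matches: `entry` (lexicon row), `pattern`,
#'   `category`, `max_scope`, `tok_from`, `tok_to` (1-based token indices
#'   within the sentence), `cstart`, `cend` (global 0-based half-open
#'   character span).
#' @export
find_trigger_matches <- function(sentence, text, lexicon) {
  empty <- data.frame(entry = integer(0), pattern = character(0),
                      category = character(0), max_scope = integer(0),
                      tok_from = integer(0), tok_to = integer(0),
                      cstart = integer(0), cend = integer(0),
                      stringsAsFactors = FALSE)
  sent_text <- substr(text, sentence$start + 1L, sentence$end)
  if (!nzchar(sent_text)) return(empty)
  cand <- list()
  for (i in seq_along(lexicon$regex)) {
    m <- gregexpr(lexicon$regex[i], sent_text, perl = TRUE,
                  ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    keep <- len > 0L
    if (!any(keep)) next
    cand[[length(cand) + 1L]] <- data.frame(
      entry = i, pattern = lexicon$pattern[i],
      category = lexicon$category[i], max_scope = lexicon$max_scope[i],
      cstart = sentence$start + as.integer(m[keep]) - 1L,
      cend = sentence$start + as.integer(m[keep]) - 1L + len[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)

  # pseudo precedence: negation matches contained in a pseudo match die
  pse <- cand[cand$category == "pseudo", , drop = FALSE]
  if (nrow(pse)) {
    neg <- grepl("^negation_", cand$category)
    contained <- vapply(seq_len(nrow(cand)), function(j) {
      neg[j] && any(cand$cstart[j] >= pse$cstart & cand$cend[j] <= pse$cend)
    }, logical(1))
    cand <- cand[!contained, , drop = FALSE]
  }
  if (!nrow(cand)) return(empty)

  # longest-match-first greedy overlap resolution
  cand <- cand[order(-(cand$cend - cand$cstart), cand$cstart, cand$entry), ,
               drop = FALSE]
  kept <- logical(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    overlaps <- kept & cand$cstart < cand$cend[j] & cand$cend > cand$cstart[j]
    if (!any(overlaps)) kept[j] <- TRUE
  }
  cand <- cand[kept, , drop = FALSE]

  toks <- sentence$tokens
  tok_from <- tok_to <- integer(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    hit <- which(toks$start < cand$cend[j] & toks$end > cand$cstart[j])
    if (!length(hit)) { tok_from[j] <- NA_integer_; next }
    tok_from[j] <- min(hit); tok_to[j] <- max(hit)
  }
  cand$tok_from <- tok_from; cand$tok_to <- tok_to
  cand <- cand[!is.na(cand$tok_from), , drop = FALSE]
  cand <- cand[order(cand$cstart), , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("entry", "pattern", "category", "max_scope",
           "tok_from", "tok_to", "cstart", "cend")]
}

#' Compute the scope of a negation trigger
#'
#' The default scope is the remainder of the sentence after (forward) or
#' before (backward) the trigger. The scope is truncated at the nearest
#' termination match in the scope direction (termination tokens excluded)
#' and, when the entry defines `max_scope`, further truncated to that
#' many words (punctuation tokens are not counted as words).
#'
#' @param match One row of [find_trigger_matches()] output (a negation
#'   trigger).
#' @param sentence The sentence span the match came from.
#' @param terminations Data frame of termination matches in the same
#'   sentence (may be empty).
#' @return `list(direction, from, to)`: 1-based inclusive token range
#'   within the sentence; `from > to` encodes an empty scope. Scopes
#'   never cross the sentence boundary.
#' @export
compute_scope <- function(match, sentence, terminations = NULL) {
  stopifnot(grepl("^negation_", match$category))
  ntok <- nrow(sentence$tokens)
  forward <- match$category == "negation_forward"
  if (forward) {
    from <- match$tok_to + 1L; to <- ntok
    if (!is.null(terminations) && nrow(terminations)) {
      after <- terminations$tok_from[terminations$tok_from > match$tok_to]
      if (length(after)) to <- min(to, min(after) - 1L)
    }
  } else {
    from <- 1L; to <- match$tok_from - 1L
    if (!is.null(terminations) && nrow(terminations)) {
      before <- terminations$tok_to[terminations$tok_to < match$tok_from]
      if (length(before)) from <- max(from, max(before) + 1L)
    }
  }
  ms <- match$max_scope
  if (!is.na(ms) && from <= to) {
    idx <- from:to
    words <- idx[is_word_token(sentence$tokens$token[idx])]
    if (forward) {
      if (length(words) > ms) to <- words[ms] else to <- to
    } else {
      if (length(words) > ms) from <- words[length(words) - ms + 1L]
    }
  }
  list(direction = if (forward) "forward" else "backward",
       from = from, to = to)
}

#' Rule-based negation classification of a document's entities
#'
#' An entity is *negated* iff at least one of its tokens lies inside at
#' least one negation scope (negation from any one scope suffices); all
#' other entities are *not negated*. An entity whose span overlaps the
#' trigger's own match is not negated by that trigger (a trigger does not
#' negate itself). Entities and triggers only interact within the same
#' sentence; an entity belongs to the sentence containing its first
#' token.
#'
#' @param doc An `annotated_document`.
#' @param lexicon A compiled `trigger_lexicon`.
#' @param splitter Optional sentence-splitting function
#'   `function(text) -> list of sentence spans` (see [split_sentences()]);
#'   `NULL` uses the default rule-based splitter.
#' @param split_minus Preprocessing flag: detach trailing hyphens during
#'   tokenization (only used by the default splitter).
#' @return Data frame of predictions: `doc_id`, `entity_index`, `label`,
#'   `probability` (always `NA`: the rule engine emits hard labels),
#'   `method = "rule"`.
#' @export
classify_entities_rule <- function(doc, lexicon, splitter = NULL,
                                   split_minus = FALSE) {
  sentences <- if (is.null(splitter)) {
    split_sentences(doc$text, split_minus = split_minus)
  } else splitter(doc$text)
  n_ent <- length(doc$entities)
  negated <- logical(n_ent)
  if (n_ent && length(sentences)) {
    # entity -> sentence assignment by first overlapping token
    ent_sent <- rep(NA_integer_, n_ent)
    ent_toks <- vector("list", n_ent)
    for (k in seq_len(n_ent)) {
      e <- doc$entities[[k]]
      for (s in seq_along(sentences)) {
        toks <- sentences[[s]]$tokens
        hit <- which(toks$start < e$end & toks$end > e$start)
        if (length(hit)) { ent_sent[k] <- s; ent_toks[[k]] <- hit; break }
      }
    }
    for (s in seq_along(sentences)) {
      here <- which(ent_sent == s)
      if (!length(here)) next
      matches <- find_trigger_matches(sentences[[s]], doc$text, lexicon)
      negs <- matches[grepl("^negation_", matches$category), , drop = FALSE]
      if (!nrow(negs)) next
      terms <- matches[matches$category == "termination", , drop = FALSE]
      for (j in seq_len(nrow(negs))) {
        sc <- compute_scope(negs[j, ], sentences[[s]], terms)
        if (sc$from > sc$to) next
        for (k in here) {
          e <- doc$entities[[k]]
          if (e$start < negs$cend[j] && e$end > negs$cstart[j]) next
          if (any(ent_toks[[k]] >= sc$from & ent_toks[[k]] <= sc$to))
            negated[k] <- TRUE
        }
      }
    }
  }
  data.frame(doc_id = rep(doc$doc_id, n_ent),
             entity_index = seq_len(n_ent),
             label = ifelse(negated, "negated", "not_negated"),
             probability = rep(NA_real_, n_ent),
             method = rep("rule", n_ent),
             stringsAsFactors = FALSE)
}

#' Rule-based classification of a whole corpus
#'
#' @param docs Corpus.
#' @inheritParams classify_entities_rule
#' @return Row-bound predictions of [classify_entities_rule()].
#' @export
annotate_corpus_rule <- function(docs, lexicon = default_lexicon(),
                                 splitter = NULL, split_minus = FALSE) {
  out <- do.call(rbind, lapply(docs, classify_entities_rule,
                               lexicon = lexicon, splitter = splitter,
                               split_minus = split_minus))
  if (is.null(out))
    out <- data.frame(doc_id = character(0), entity_index = integer(0),
                      label = character(0), probability = numeric(0),
                      method = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
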