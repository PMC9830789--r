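# Independent brute-force oracle for trigger/scope semantics, plus small
# fixture builders. The oracle deliberately follows a different path from
# the engine: token-subsequence phrase matching over a simple
# whitespace-and-peel tokenizer, with the scope definition applied
# literally to every (trigger occurrence, entity) pair.

# peel punctuation off whitespace words; a single trailing "-" after a
# letter/digit stays attached (the clinical minus shorthand)
oracle_tokenize <- function(sent_text, sent_start) {
  m <- gregexpr("\\S+", sent_text, perl = TRUE)[[1]]
  toks <- list()
  if (m[1] == -1L) return(toks)
  len <- attr(m, "match.length")
  for (i in seq_along(m)) {
    w <- substring(sent_text, m[i], m[i] + len[i] - 1L)
    off <- sent_start + m[i] - 1L          # 0-based global offset
    chars <- strsplit(w, "", fixed = TRUE)[[1]]
    alnum <- grepl("[[:alnum:]]", chars)
    j <- 1L
    while (j <= length(chars)) {
      if (alnum[j]) {
        k <- j
        while (k < length(chars) && alnum[k + 1L]) k <- k + 1L
        if (k < length(chars) && chars[k + 1L] == "-" &&
            (k + 1L == length(chars) || !alnum[k + 2L])) k <- k + 1L
        toks[[length(toks) + 1L]] <- list(
          token = paste(chars[j:k], collapse = ""),
          start = off + j - 1L, end = off + k)
        j <- k + 1L
      } else {
        toks[[length(toks) + 1L]] <- list(token = chars[j],
                                          start = off + j - 1L,
                                          end = off + j)
        j <- j + 1L
      }
    }
  }
  toks
}

oracle_sentences <- function(text) {
  bounds <- gregexpr("[.!?]+|\n", text, perl = TRUE)[[1]]
  cuts <- if (bounds[1] == -1L) integer(0)
          else as.integer(bounds) + attr(bounds, "match.length") - 1L
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(text))
  out <- list()
  for (i in seq_along(starts)) {
    if (starts[i] > ends[i]) next
    seg <- substring(text, starts[i], ends[i])
    if (!nzchar(trimws(seg))) next
    out[[length(out) + 1L]] <- list(text = seg, start = starts[i] - 1L)
  }
  out
}

# entries: list of list(words = character vector, category, max_scope)
oracle_doc_labels <- function(doc, entries) {
  labels <- rep("not_negated", length(doc$entities))
  for (sent in oracle_sentences(doc$text)) {
    toks <- oracle_tokenize(sent$text, sent$start)
    if (!length(toks)) next
    words <- tolower(vapply(toks, `[[`, character(1), "token"))
    # every phrase occurrence, all categories
    occ <- list()
    for (ei in seq_along(entries)) {
      p <- tolower(entries[[ei]]$words); L <- length(p)
      if (L > length(words)) next
      for (s in seq_len(length(words) - L + 1L))
        if (all(words[s:(s + L - 1L)] == p))
          occ[[length(occ) + 1L]] <- list(from = s, to = s + L - 1L,
                                          entry = entries[[ei]])
    }
    if (!length(occ)) next
    is_cat <- function(o, cats) o$entry$category %in% cats
    pse <- Filter(function(o) is_cat(o, "pseudo"), occ)
    occ <- Filter(function(o) {
      if (!is_cat(o, c("negation_forward", "negation_backward"))) return(TRUE)
      !any(vapply(pse, function(q) o$from >= q$from && o$to <= q$to,
                  logical(1)))
    }, occ)
    # longest first, drop overlaps with already-kept occurrences
    ord <- order(-vapply(occ, function(o) o$to - o$from, numeric(1)),
                 vapply(occ, `[[`, numeric(1), "from"))
    kept <- list()
    for (o in occ[ord]) {
      clash <- any(vapply(kept, function(k) o$from <= k$to && o$to >= k$from,
                          logical(1)))
      if (!clash) kept[[length(kept) + 1L]] <- o
    }
    terms <- Filter(function(o) is_cat(o, "termination"), kept)
    negs <- Filter(function(o) is_cat(o, c("negation_forward",
                                           "negation_backward")), kept)
    ent_tok <- lapply(doc$entities, function(e) {
      which(vapply(toks, function(t) t$start < e$end && t$end > e$start,
                   logical(1)))
    })
    for (o in negs) {
      fwd <- o$entry$category == "negation_forward"
      if (fwd) {
        from <- o$to + 1L; to <- length(words)
        aft <- vapply(terms, `[[`, numeric(1), "from")
        aft <- aft[aft > o$to]
        if (length(aft)) to <- min(to, min(aft) - 1L)
      } else {
        from <- 1L; to <- o$from - 1L
        bef <- vapply(terms, `[[`, numeric(1), "to")
        bef <- bef[bef < o$from]
        if (length(bef)) from <- max(from, max(bef) + 1L)
      }
      ms <- o$entry$max_scope
      if (!is.null(ms) && !is.na(ms) && from <= to) {
        idx <- from:to
        w_idx <- idx[grepl("[[:alnum:]]",
                           vapply(toks[idx], `[[`, character(1), "token"))]
        if (fwd) { if (length(w_idx) > ms) to <- w_idx[ms] }
        else if (length(w_idx) > ms) from <- w_idx[length(w_idx) - ms + 1L]
      }
      if (from > to) next
      o_span <- c(toks[[o$from]]$start, toks[[o$to]]$end)
      for (k in seq_along(doc$entities)) {
        e <- doc$entities[[k]]
        if (e$start < o_span[2] && e$end > o_span[1]) next
        if (any(ent_tok[[k]] >= from & ent_tok[[k]] <= to))
          labels[k] <- "negated"
      }
    }
  }
  labels
}

lexicon_to_oracle_entries <- function(patterns, categories,
                                      max_scopes = NULL) {
  lapply(seq_along(patterns), function(i) list(
    words = strsplit(patterns[i], " ", fixed = TRUE)[[1]],
    category = categories[i],
    max_scope = if (is.null(max_scopes)) NULL else max_scopes[i]))
}

grammar_to_oracle_entries <- function(grammar) {
  c(lapply(grammar$forward, function(g)
      list(words = g$tokens, category = "negation_forward")),
    lapply(grammar$backward, function(g)
      list(words = g$tokens, category = "negation_backward")),
    lapply(grammar$pseudo, function(p)
      list(words = p, category = "pseudo")),
    lapply(grammar$termination, function(t)
      list(words = t, category = "termination")))
}

# build a document from word tokens joined by single spaces, entities
# given as 1-based token ranges
doc_from_tokens <- function(tokens, ent_ranges, doc_id = "t1",
                            category = "general_practitioner",
                            gold = NULL) {
  starts <- cumsum(c(0L, nchar(tokens) + 1L))[seq_along(tokens)]
  text <- paste(tokens, collapse = " ")
  ents <- lapply(seq_along(ent_ranges), function(i) {
    r <- ent_ranges[[i]]
    s <- starts[r[1]]
    e <- starts[r[length(r)]] + nchar(tokens[r[length(r)]])
    entity_annotation(s, e, substr(text, s + 1L, e),
                      gold_label = if (is.null(gold)) NULL else gold[i])
  })
  annotated_document(doc_id, text, category, ents)
}

# random rule-world draw used by the property and equivalence tests
random_rule_case <- function(max_tokens = 12L) {
  fillers <- c("pols", "been", "arm", "romp", "oog", "oor", "huid", "nek")
  ent_words <- c("koorts", "pijn", "oedeem", "icterus", "anemie")
  trig_pool <- list(
    list(p = "geen", cat = "negation_forward"),
    list(p = "geen spoor van", cat = "negation_forward"),
    list(p = "zonder", cat = "negation_forward"),
    list(p = "uitgesloten", cat = "negation_backward"),
    list(p = "afwezig", cat = "negation_backward"))
  n_trig <- sample(2:4, 1)
  trig <- trig_pool[sample.int(length(trig_pool), n_trig)]
  patterns <- vapply(trig, `[[`, character(1), "p")
  categories <- vapply(trig, `[[`, character(1), "cat")
  max_scopes <- ifelse(stats::runif(n_trig) < 0.3,
                       sample(1:3, n_trig, replace = TRUE), NA)
  if (stats::runif(1) < 0.5) {
    patterns <- c(patterns, "maar"); categories <- c(categories, "termination")
    max_scopes <- c(max_scopes, NA)
  }
  if (stats::runif(1) < 0.4) {
    patterns <- c(patterns, "geen spoor")
    categories <- c(categories, "pseudo")
    max_scopes <- c(max_scopes, NA)
  }
  n_tok <- sample(3:max_tokens, 1)
  pool <- c(fillers, ent_words, unlist(strsplit(patterns, " ")), ",", "maar")
  tokens <- sample(pool, n_tok, replace = TRUE)
  cand <- which(tokens %in% c(ent_words, fillers))
  ent_at <- if (length(cand) <= 2L) cand
            else sort(sample(cand, 2L))
  if (!length(ent_at)) { tokens[1] <- ent_words[1]; ent_at <- 1L }
  entries <- lapply(seq_along(patterns), function(i)
    trigger_entry(patterns[i], categories[i],
                  max_scope = if (is.na(max_scopes[i])) NULL
                              else max_scopes[i]))
  list(doc = doc_from_tokens(tokens, as.list(ent_at)),
       lexicon = compile_lexicon(entries),
       oracle_entries = lexicon_to_oracle_entries(patterns, categories,
                                                  max_scopes))
}

expect_rule_matches_oracle <- function(case) {
  got <- classify_entities_rule(case$doc, case$lexicon)$label
  want <- oracle_doc_labels(case$doc, case$oracle_entries)
  expect_identical(got, want)
}
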