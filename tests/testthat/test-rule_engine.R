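lex_en <- function() {
  compile_lexicon(list(trigger_entry("no signs of", "negation_forward"),
                       trigger_entry("but", "termination")))
}

test_that("lexicon compilation validates entries", {
  lex <- compile_lexicon(list(trigger_entry("geen", "negation_forward"),
                              trigger_entry("maar", "termination")))
  expect_s3_class(lex, "trigger_lexicon")
  expect_length(lex$pattern, 2L)
  expect_error(compile_lexicon(list()), "configuration error")
  expect_error(compile_lexicon(list(
    trigger_entry("geen", "negation_forward"),
    trigger_entry("geen", "negation_forward"))), "duplicate.*geen")
  expect_error(compile_lexicon(list(
    trigger_entry("niet(", "negation_forward"))), "does not compile")
  expect_error(trigger_entry("", "pseudo"), "empty pattern")
  expect_error(trigger_entry("geen", "negation_forward", max_scope = 0),
               "max_scope")
  expect_error(trigger_entry("maar", "termination", max_scope = 2),
               "negation categories")
})

test_that("the packaged lexicon compiles with its full entry count", {
  path <- system.file("extdata", "lexicon_nl.tsv", package = "negdetect")
  lines <- readLines(path)
  n_expected <- sum(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  lex <- default_lexicon()
  expect_identical(length(lex$pattern), n_expected)
  expect_setequal(unique(lex$category),
                  c("negation_forward", "negation_backward", "pseudo",
                    "termination"))
})

test_that("pseudo-triggers take precedence over contained negations", {
  lex <- compile_lexicon(list(trigger_entry("niet", "negation_forward"),
                              trigger_entry("niet alleen", "pseudo")))
  s <- split_sentences("niet alleen pijn")[[1]]
  m <- find_trigger_matches(s, "niet alleen pijn", lex)
  expect_identical(nrow(m), 1L)
  expect_identical(m$category, "pseudo")
  # no trigger substring at all
  none <- find_trigger_matches(split_sentences("alles rustig")[[1]],
                               "alles rustig", lex)
  expect_identical(nrow(none), 0L)
})

test_that("the longest of overlapping matches wins", {
  lex <- compile_lexicon(list(
    trigger_entry("no", "negation_forward"),
    trigger_entry("no evidence of", "negation_forward")))
  text <- "no evidence of fracture"
  m <- find_trigger_matches(split_sentences(text)[[1]], text, lex)
  expect_identical(nrow(m), 1L)
  expect_identical(m$pattern, "no evidence of")
  # matching is case-insensitive
  m2 <- find_trigger_matches(split_sentences(toupper(text))[[1]],
                             toupper(text), lex)
  expect_identical(m2$pattern, "no evidence of")
})

test_that("scopes follow direction, terminations and max_scope", {
  text <- "No signs of infection, but pneumonia persists"
  s <- split_sentences(text)[[1]]
  m <- find_trigger_matches(s, text, lex_en())
  neg <- m[m$category == "negation_forward", ]
  terms <- m[m$category == "termination", ]
  # default forward scope: remainder of the sentence
  sc_all <- compute_scope(neg, s)
  expect_identical(sc_all[c("from", "to")], list(from = 4L, to = 8L))
  # termination truncates (tokens: No signs of infection , but ...)
  sc <- compute_scope(neg, s, terms)
  expect_identical(sc[c("from", "to")], list(from = 4L, to = 5L))
  # trigger at the final token: empty scope
  t2 <- "koorts is afwezig"
  lexb <- compile_lexicon(list(trigger_entry("afwezig", "negation_backward"),
                               trigger_entry("geen", "negation_forward")))
  s2 <- split_sentences(t2)[[1]]
  m2 <- find_trigger_matches(s2, t2, lexb)
  scb <- compute_scope(m2, s2)
  expect_identical(scb$direction, "backward")
  expect_identical(scb[c("from", "to")], list(from = 1L, to = 2L))
  t3 <- "alles wijst op geen"
  s3 <- split_sentences(t3)[[1]]
  m3 <- find_trigger_matches(s3, t3, lexb)
  sc3 <- compute_scope(m3[m3$category == "negation_forward", ], s3)
  expect_true(sc3$from > sc3$to)
  # max_scope in words
  lexms <- compile_lexicon(list(
    trigger_entry("geen", "negation_forward", max_scope = 2)))
  t4 <- "geen a b c d e"
  s4 <- split_sentences(t4)[[1]]
  sc4 <- compute_scope(find_trigger_matches(s4, t4, lexms), s4)
  expect_identical(sc4[c("from", "to")], list(from = 2L, to = 3L))
})

test_that("classification matches the documented worked examples", {
  text <- "No signs of infection, but pneumonia persists"
  doc <- annotated_document("d1", text, "radiology_report", list(
    entity_annotation(12, 21, "infection"),
    entity_annotation(27, 36, "pneumonia")))
  pred <- classify_entities_rule(doc, lex_en())
  expect_identical(pred$label, c("negated", "not_negated"))
  expect_identical(unique(pred$method), "rule")
  expect_true(all(is.na(pred$probability)))
  # default sentence scope over-reaches on the list construction
  lexg <- compile_lexicon(list(trigger_entry("geen", "negation_forward")))
  t2 <- "geen buikpijn, schaafwond aan been"
  d2 <- annotated_document("d2", t2, "general_practitioner", list(
    entity_annotation(5, 13, "buikpijn"),
    entity_annotation(15, 25, "schaafwond")))
  expect_identical(classify_entities_rule(d2, lexg)$label,
                   c("negated", "negated"))
  # zero triggers: everything not negated
  d3 <- annotated_document("d3", "alles rustig vandaag", "radiology_report",
                           list(entity_annotation(6, 12, "rustig")))
  expect_identical(classify_entities_rule(d3, lexg)$label, "not_negated")
})

test_that("a trigger never negates an entity overlapping itself", {
  lex <- compile_lexicon(list(
    trigger_entry("geen eetlust", "negation_forward"),
    trigger_entry("geen", "negation_forward")))
  text <- "geen eetlust vandaag"
  doc <- annotated_document("d", text, "general_practitioner", list(
    entity_annotation(5, 12, "eetlust")))
  # "geen eetlust" wins as longest; the entity overlaps it, and must not
  # be negated by the phrase containing it
  expect_identical(classify_entities_rule(doc, lex)$label, "not_negated")
})

test_that("sentence boundaries contain trigger effects", {
  lex <- compile_lexicon(list(trigger_entry("geen", "negation_forward")))
  text <- "geen koorts. wel buikpijn"
  doc <- annotated_document("d", text, "general_practitioner", list(
    entity_annotation(5, 11, "koorts"),
    entity_annotation(17, 25, "buikpijn")))
  expect_identical(classify_entities_rule(doc, lex)$label,
                   c("negated", "not_negated"))
  # a splitter is an injection point: treat the whole text as one sentence
  one_sentence <- function(text) {
    toks <- tokenize_spans(text)
    list(list(start = 0L, end = nchar(text), tokens = toks))
  }
  expect_identical(
    classify_entities_rule(doc, lex, splitter = one_sentence)$label,
    c("negated", "negated"))
})

test_that("rule engine equals the brute-force oracle on random draws", {
  set.seed(91)
  for (i in 1:120) expect_rule_matches_oracle(random_rule_case())
})

test_that("pseudo and termination additions never grow the negated set", {
  set.seed(17)
  base_entries <- list(trigger_entry("geen", "negation_forward"),
                       trigger_entry("zonder", "negation_forward"))
  base <- compile_lexicon(base_entries)
  with_pseudo <- compile_lexicon(c(base_entries, list(
    trigger_entry("geen enkele", "pseudo"))))
  with_term <- compile_lexicon(c(base_entries, list(
    trigger_entry("maar", "termination"))))
  pool <- c("geen", "zonder", "enkele", "maar", "koorts", "pijn", "arm",
            "been", ",")
  for (i in 1:200) {
    n <- sample(3:10, 1)
    tokens <- sample(pool, n, replace = TRUE)
    ents <- which(tokens %in% c("koorts", "pijn"))
    if (!length(ents)) { tokens[n] <- "koorts"; ents <- n }
    doc <- doc_from_tokens(tokens, as.list(ents))
    neg0 <- which(classify_entities_rule(doc, base)$label == "negated")
    negp <- which(classify_entities_rule(doc, with_pseudo)$label == "negated")
    negt <- which(classify_entities_rule(doc, with_term)$label == "negated")
    expect_true(all(negp %in% neg0))
    expect_true(all(negt %in% neg0))
  }
})

test_that("classification is deterministic", {
  gen <- generate_corpus(generator_config(n_documents = 15, seed = 5))
  p1 <- annotate_corpus_rule(gen$corpus)
  p2 <- annotate_corpus_rule(gen$corpus)
  expect_identical(p1, p2)
})

test_that("lexicon TSV reader parses categories, scopes and comments", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "geen\tnegation_forward\t3",
               "maar\ttermination", ""), f)
  lex <- read_lexicon(f)
  expect_identical(length(lex$pattern), 2L)
  expect_identical(lex$max_scope, c(3L, NA_integer_))
})
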