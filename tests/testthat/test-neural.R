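# -- BPE ---------------------------------------------------------------

test_that("BPE learns merges by pair frequency with lexicographic ties", {
  # brute-force pair count for "aaab aaab": (a,a) x4, (a,b) x2 -> merge (a,a)
  tok <- train_bpe("aaab aaab", vocab_size = 4)
  expect_identical(tok$merges, "a\ra")
  expect_identical(bpe_encode(tok, "aaab"), c("aa", "a", "b"))
  # vocab_size == alphabet: zero merges, characters out
  tok0 <- train_bpe("abc abc", vocab_size = 4)  # alphabet: space a b c
  expect_length(tok0$merges, 0L)
  expect_identical(bpe_encode(tok0, "abc"), c("a", "b", "c"))
  expect_error(train_bpe("abc", vocab_size = 2), "configuration error")
})

test_that("BPE tokenization is invertible on any input over the alphabet", {
  texts <- c("geen aanwijzing voor pneumonie",
             "status na controle, beloop rustig",
             "RR 120/80, pols 80")
  tok <- train_bpe(texts, vocab_size = 40)
  set.seed(7)
  alphabet <- setdiff(tok$alphabet, " ")
  for (i in 1:50) {
    w <- paste(sample(alphabet, sample(1:12, 1), replace = TRUE),
               collapse = "")
    expect_identical(bpe_decode(bpe_encode(tok, w)), w)
  }
  # whole sentences, whitespace included, also invert exactly
  for (t in texts)
    expect_identical(bpe_decode(bpe_encode(tok, t)), t)
  # characters never seen at training time pass through (as OOV singles)
  expect_identical(bpe_decode(bpe_encode(tok, "sinusopathie?")),
                   "sinusopathie?")
})

test_that("BPE training is deterministic", {
  texts <- c("misselijkheid na inspanning", "geen misselijkheid vandaag")
  t1 <- train_bpe(texts, vocab_size = 35)
  t2 <- train_bpe(texts, vocab_size = 35)
  expect_identical(t1, t2)
})

# -- windowing / placeholder abstraction -------------------------------

test_that("abstract_entity windows and clips around the placeholder", {
  toks <- c("no", "signs", "of", "diabetes", "mellitus")
  win <- abstract_entity(toks, c(4L, 5L))
  expect_identical(as.character(win), c("no", "signs", "of", "[TERM]"))
  expect_identical(attr(win, "placeholder_pos"), 4L)
  # entity covering everything
  all_win <- abstract_entity(toks, c(1L, 5L))
  expect_identical(as.character(all_win), "[TERM]")
  expect_error(abstract_entity(toks, c(3L, 2L)), "empty or outside")
  # left clipping follows max(1, i - left_tokens)
  long <- sprintf("w%02d", 1:40)
  for (i in c(2L, 16L, 40L)) {
    w <- abstract_entity(long, c(i, i))
    left_expected <- long[seq(max(1L, i - 15L), i - 1L)]
    expect_identical(as.character(w),
                     c(left_expected, "[TERM]",
                       long[seq_len(min(40L, i + 10L) - i) + i]))
    # window containment invariant
    expect_lte(length(w), 15L + 1L + 10L)
  }
})

test_that("two entities differing only in surface give identical inputs", {
  mk <- function(term) {
    n <- nchar(term)
    annotated_document(
      paste0("d_", term), sprintf("geen tekenen van %s vandaag", term),
      "general_practitioner",
      list(entity_annotation(17L, 17L + n, term, gold_label = "negated")))
  }
  tok <- train_bpe(c("geen tekenen van iets vandaag"), vocab_size = 30)
  exs <- build_training_examples(list(mk("flebralgie"), mk("cardiopathie")),
                                 tokenizer = tok)
  expect_identical(exs[[1]]$tokens, exs[[2]]$tokens)
  expect_identical(exs[[1]]$placeholder_index, exs[[2]]$placeholder_index)
})

# -- CBOW --------------------------------------------------------------

test_that("CBOW returns finite vectors per token and is deterministic", {
  texts <- rep(c("geen koorts bij patient", "koorts bij controle gezien"),
               10)
  e1 <- pretrain_cbow(texts, dim = 8, seed = 4, epochs = 3)
  expect_identical(nrow(e1), 6L)   # 6 distinct tokens
  expect_identical(ncol(e1), 8L)
  expect_true(all(is.finite(e1)))
  e2 <- pretrain_cbow(texts, dim = 8, seed = 4, epochs = 3)
  expect_identical(unclass(e1), unclass(e2))
  expect_error(pretrain_cbow(texts, dim = 0), "configuration error")
})

test_that("CBOW training loss decreases on a 200-sentence corpus", {
  set.seed(12)
  gen <- generate_corpus(generator_config(n_documents = 60, seed = 12))
  sents <- unlist(lapply(gen$corpus, function(d)
    strsplit(d$text, "\n", fixed = TRUE)[[1]]))[1:200]
  emb <- pretrain_cbow(sents, dim = 16, seed = 2, epochs = 5)
  hist <- attr(emb, "loss_history")
  expect_lt(hist[length(hist)], hist[1])
})

# -- classifier --------------------------------------------------------

tiny_example <- function(tokens, label, id = "d", k = 1L) {
  structure(list(tokens = tokens, placeholder_index = match("[TERM]", tokens),
                 label = label, doc_id = id, entity_index = k),
            class = "training_example")
}

test_that("training validates class coverage and memorizes a tiny set", {
  neg <- tiny_example(c("geen", "[TERM]"), "negated")
  pos <- tiny_example(c("duidelijke", "[TERM]"), "not_negated")
  expect_error(train_classifier(rep(list(neg), 4)),
               "validation error.*not_negated")
  set.seed(0)
  model <- train_classifier(
    c(rep(list(neg), 10), rep(list(pos), 10)),
    hyperparams = list(embedding_dim = 12L, hidden_size = 8L, fc_hidden = 6L,
                       epochs = 60L, lr = 1e-2, batch_size = 4L),
    seed = 2)
  # training loss decreases
  expect_lt(model$loss_history[length(model$loss_history)],
            model$loss_history[1])
  pred <- predict(model, list(neg, pos))
  expect_identical(pred$label, c("negated", "not_negated"))
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_identical(unique(pred$method), "bilstm")
})

test_that("training and prediction are deterministic under a seed", {
  neg <- tiny_example(c("geen", "[TERM]"), "negated")
  pos <- tiny_example(c("wel", "[TERM]"), "not_negated")
  hp <- list(embedding_dim = 6L, hidden_size = 4L, fc_hidden = 3L,
             epochs = 5L)
  exs <- c(rep(list(neg), 5), rep(list(pos), 5))
  m1 <- train_classifier(exs, hyperparams = hp, seed = 9)
  m2 <- train_classifier(exs, hyperparams = hp, seed = 9)
  expect_identical(predict(m1, exs), predict(m2, exs))
})

test_that("probability 0.5 maps to negated and OOV tokens never fail", {
  neg <- tiny_example(c("geen", "[TERM]"), "negated")
  pos <- tiny_example(c("wel", "[TERM]"), "not_negated")
  model <- train_classifier(
    c(rep(list(neg), 3), rep(list(pos), 3)),
    hyperparams = list(embedding_dim = 5L, hidden_size = 3L, fc_hidden = 2L,
                       epochs = 2L), seed = 1)
  # force the exact threshold output: zero head -> sigmoid(0) = 0.5
  model$params$W2[] <- 0; model$params$b2 <- 0
  pred <- predict(model, list(neg))
  expect_identical(pred$probability, 0.5)
  expect_identical(pred$label, "negated")
  # unseen tokens map to the reserved unknown id
  oov <- tiny_example(c("zzz", "qqq", "[TERM]"), NULL)
  expect_no_error(predict(model, list(oov)))
})

test_that("a saved model directory restores an identical classifier", {
  gen <- generate_corpus(generator_config(n_documents = 40, seed = 21))
  model <- train_bilstm(
    gen$corpus, vocab_size = 60,
    hyperparams = list(embedding_dim = 10L, hidden_size = 6L, fc_hidden = 4L,
                       epochs = 2L), seed = 3)
  dir <- withr::local_tempdir()
  save_classifier(model, dir)
  back <- load_classifier(dir)
  p1 <- predict_corpus_bilstm(model, gen$corpus)
  p2 <- predict_corpus_bilstm(back, gen$corpus)
  expect_equal(p1, p2, tolerance = 1e-12)
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_identical(manifest$schema, "negdetect-bilstm")
})
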