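pred_df <- function(keys, labels, method = "m") {
  data.frame(doc_id = vapply(keys, `[[`, character(1), 1),
             entity_index = as.integer(vapply(keys, `[[`, character(1), 2)),
             label = labels, probability = NA_real_, method = method,
             stringsAsFactors = FALSE)
}
keyed <- function(n) lapply(seq_len(n), function(i) c("d", as.character(i)))

test_that("fold sizes follow integer division and stay deterministic", {
  f <- make_folds(seq_len(12419), cv_config(k = 10, seed = 1, "entity"))
  sizes <- sort(as.integer(table(f)), decreasing = TRUE)
  expect_identical(sizes, c(rep(1242L, 9), 1241L))
  expect_identical(
    f, make_folds(seq_len(12419), cv_config(k = 10, seed = 1, "entity")))
  # ten items, ten singleton folds
  expect_identical(sort(as.integer(table(
    make_folds(1:10, cv_config(10, 3, "entity"))))), rep(1L, 10))
  expect_error(make_folds(1:5, cv_config(10, 1, "entity")),
               "configuration error")
})

test_that("folds partition items; record grouping keeps records whole", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(30:300, 1)
    k <- sample(2:10, 1)
    f <- make_folds(seq_len(n), cv_config(k, sample.int(1e6, 1), "entity"))
    expect_identical(length(f), n)
    expect_setequal(unique(f), seq_len(k))
    expect_lte(diff(range(table(f))), 1)
  }
  doc_ids <- rep(sprintf("r%02d", 1:20), times = sample(1:5, 20, TRUE))
  fr <- make_folds(doc_ids, cv_config(5, 7, "record"))
  split_check <- tapply(fr, doc_ids, function(x) length(unique(x)))
  expect_true(all(split_check == 1L))
})

test_that("majority vote equals exhaustive enumeration on all 8 combos", {
  combos <- expand.grid(a = negation_labels(), b = negation_labels(),
                        c = negation_labels(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    votes <- unlist(combos[i, ])
    preds <- rbind(pred_df(keyed(1), votes[1], "m1"),
                   pred_df(keyed(1), votes[2], "m2"),
                   pred_df(keyed(1), votes[3], "m3"))
    out <- majority_vote(preds)
    # independent oracle: count table over the three labels
    tab <- sort(table(votes), decreasing = TRUE)
    expect_identical(out$label, names(tab)[1])
    expect_identical(out$method, "ensemble")
    expect_true(is.na(out$probability))
  }
  # wrong arity is a validation error naming the entity
  two <- rbind(pred_df(keyed(1), "negated", "m1"),
               pred_df(keyed(1), "negated", "m2"))
  expect_error(majority_vote(two), "validation error.*doc d.*index 1")
})

test_that("metrics match hand arithmetic and the undefined conventions", {
  gold <- data.frame(doc_id = "d", entity_index = 1:6,
                     gold_label = c("negated", "negated", "negated",
                                    "not_negated", "not_negated",
                                    "not_negated"),
                     stringsAsFactors = FALSE)
  # tp=2 fp=1 fn=1 tn=2 -> precision = recall = f1 = 2/3
  pred <- pred_df(keyed(6), c("negated", "negated", "not_negated",
                              "negated", "not_negated", "not_negated"))
  m <- compute_metrics(pred, gold, stratify_by_category = FALSE)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  # perfect predictions
  mp <- compute_metrics(pred_df(keyed(6), gold$gold_label), gold,
                        stratify_by_category = FALSE)
  expect_identical(c(mp$precision, mp$recall, mp$f1), c(1, 1, 1))
  # zero predicted positives: precision absent (NA), recall 0
  mz <- compute_metrics(pred_df(keyed(6), rep("not_negated", 6)), gold,
                        stratify_by_category = FALSE)
  expect_true(is.na(mz$precision))
  expect_identical(mz$recall, 0)
  # coverage violations
  expect_error(compute_metrics(pred[-1, ], gold), "no prediction")
  extra <- rbind(pred, pred_df(list(c("x", "9")), "negated"))
  expect_error(compute_metrics(extra, gold), "without gold")
})

test_that("f1 lies between precision and recall on random counts", {
  set.seed(77)
  for (i in 1:500) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    gold <- data.frame(
      doc_id = "d", entity_index = seq_len(tp + fp + fn + 1),
      gold_label = c(rep("negated", tp + fn), rep("not_negated", fp + 1)),
      stringsAsFactors = FALSE)
    pred <- gold
    pred$label <- c(rep("negated", tp), rep("not_negated", fn),
                    rep("negated", fp), "not_negated")
    m <- compute_metrics(pred[, c("doc_id", "entity_index", "label")],
                         gold, stratify_by_category = FALSE)
    if (is.na(m$f1)) next
    expect_gte(m$f1 + 1e-12, min(m$precision, m$recall))
    expect_lte(m$f1 - 1e-12, max(m$precision, m$recall))
    if (m$precision == m$recall) expect_equal(m$f1, m$precision)
  }
})

test_that("metrics stratify per record category plus all", {
  gen <- generate_corpus(generator_config(n_documents = 120, seed = 9))
  gold <- corpus_entities(gen$corpus)
  preds <- annotate_corpus_rule(gen$corpus)
  m <- compute_metrics(preds, gold)
  expect_identical(m$stratum[1], "all")
  expect_true(all(unique(gold$category) %in% m$stratum))
  # micro counts add up across strata
  expect_identical(sum(m$tp[-1]), m$tp[1])
})

test_that("error intersections are exclusive and conserve the union", {
  r <- error_intersections(list(A = "1", B = "2", C = "3"))
  expect_identical(r$count[r$methods == "A"], 1L)
  expect_identical(r$count[r$methods == "A&B"], 0L)
  r2 <- error_intersections(list(A = c("1", "2", "3"), B = c("2", "3"),
                                 C = "3"))
  expect_identical(r2$count[r2$methods == "A"], 1L)
  expect_identical(r2$count[r2$methods == "A&B"], 1L)
  expect_identical(r2$count[r2$methods == "A&B&C"], 1L)
  r3 <- error_intersections(list(A = c("x", "y"), B = c("x", "y"),
                                 C = c("x", "y")))
  expect_identical(r3$count[r3$methods == "A&B&C"], 2L)
  expect_identical(sum(r3$count), 2L)
  set.seed(19)
  for (i in 1:25) {
    sets <- lapply(1:3, function(j)
      as.character(sample.int(30, sample(0:15, 1))))
    names(sets) <- c("a", "b", "c")
    ri <- error_intersections(sets)
    expect_identical(sum(ri$count), length(unique(unlist(sets))))
  }
})

test_that("kappa matches hand computations and is symmetric", {
  expect_identical(cohens_kappa(c("x", "y", "z"), c("x", "y", "z"))$kappa, 1)
  k0 <- cohens_kappa(c("x", "x", "y", "y"), c("x", "y", "x", "y"))
  expect_identical(k0$p_o, 0.5); expect_identical(k0$p_e, 0.5)
  expect_identical(k0$kappa, 0)
  k5 <- cohens_kappa(c("x", "x", "y", "y"), c("x", "x", "y", "x"))
  expect_identical(k5$p_o, 0.75)
  expect_identical(k5$p_e, 0.5)
  expect_identical(k5$kappa, 0.5)
  # degenerate marginals: p_e = 1 -> undefined
  expect_true(is.na(cohens_kappa(c("x", "x"), c("x", "x"))$kappa))
  expect_error(cohens_kappa("x", c("x", "y")), "validation error")
  set.seed(4)
  for (i in 1:30) {
    a <- sample(error_categories()[1:4], 12, replace = TRUE)
    b <- sample(error_categories()[1:4], 12, replace = TRUE)
    expect_equal(cohens_kappa(a, b)$kappa, cohens_kappa(b, a)$kappa)
    expect_lte(cohens_kappa(a, b)$kappa, 1)
  }
})

test_that("error report records FPs/FNs with taxonomy percentages", {
  gold <- data.frame(doc_id = "d", entity_index = 1:6,
                     gold_label = rep("not_negated", 6),
                     stringsAsFactors = FALSE)
  # zero errors -> empty report
  perfect <- error_report(list(m = pred_df(keyed(6), gold$gold_label)), gold)
  expect_identical(nrow(perfect$errors), 0L)
  # 4 FPs over two categories (3 + 1) -> 75% / 25%
  pred <- pred_df(keyed(6), c(rep("negated", 4), "not_negated",
                              "not_negated"))
  cats <- data.frame(doc_id = "d", entity_index = 1:4,
                     category = c("scope", "scope", "scope", "minus"),
                     stringsAsFactors = FALSE)
  rep4 <- error_report(list(m = pred), gold, cats)
  expect_identical(nrow(rep4$errors), 4L)
  expect_identical(unique(rep4$errors$polarity), "false_positive")
  f <- rep4$frequency
  expect_identical(f$percent[f$category == "scope"], 75)
  expect_identical(f$percent[f$category == "minus"], 25)
  expect_error(
    error_report(list(m = pred), gold,
                 data.frame(doc_id = "d", entity_index = 6,
                            category = "scope")),
    "validation error.*non-error")
  expect_error(
    error_report(list(m = pred), gold,
                 data.frame(doc_id = "d", entity_index = 1,
                            category = "typo")),
    "unknown error category")
  expect_identical(length(error_categories()), 10L)
})

test_that("minus-shorthand negations become rule-engine false negatives", {
  gen <- generate_corpus(generator_config(
    n_documents = 120, seed = 33, minus_rate = 1))
  traces <- gen$traces
  minus_ents <- traces[traces$mechanism == "minus", ]
  expect_gt(nrow(minus_ents), 5L)
  gold <- corpus_entities(gen$corpus)
  preds <- annotate_corpus_rule(gen$corpus)  # lexicon has no "-" trigger
  rep_ <- error_report(list(rule = preds), gold)
  fn <- rep_$errors[rep_$errors$polarity == "false_negative", ]
  key <- function(df) paste(df$doc_id, df$entity_index)
  expect_true(all(key(minus_ents) %in% key(fn)))
})

test_that("cross_validate shares folds and pools micro metrics", {
  gen <- generate_corpus(generator_config(n_documents = 60, seed = 13))
  res <- cross_validate(
    gen$corpus,
    train_fn = function(train_docs) default_lexicon(),
    predict_fn = function(model, test_docs)
      annotate_corpus_rule(test_docs, model),
    config = cv_config(k = 5, seed = 2, grouping = "record"))
  expect_identical(nrow(res$predictions),
                   nrow(corpus_entities(gen$corpus)))
  expect_identical(res$metrics$f1[res$metrics$stratum == "all"], 1)
  expect_identical(length(unique(res$per_fold$fold)), 5L)
})
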