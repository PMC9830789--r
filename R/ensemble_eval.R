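# Majority-voting ensemble, shared k-fold cross-validation, per-class
# and per-category metrics, error-set intersection analysis, the error
# taxonomy and inter-annotator agreement.

#' Cross-validation configuration
#'
#' Every method is evaluated on the *same* folds: the assignment depends
#' only on the items, `k` and `seed`, never on the method. Grouping
#' defaults to record-level (all entities of one record share a fold) so
#' no document text leaks between train and test folds; entity-level
#' grouping is available for comparison.
#'
#' @param k Number of folds (>= 2, default 10).
#' @param seed RNG seed for the shuffle.
#' @param grouping `"record"` or `"entity"`.
#' @return A `cv_config`.
#' @export
cv_config <- function(k = 10L, seed = 1L, grouping = c("record", "entity")) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("cv_config: k must be >= 2")
  structure(list(k = k, seed = as.integer(seed),
                 grouping = match.arg(grouping)), class = "cv_config")
}

#' Assign items to cross-validation folds
#'
#' Deterministic under the config seed; the folds partition the items
#' and their sizes differ by at most one (entity grouping; with record
#' grouping the *records* are balanced to within one and entities
#' inherit their record's fold).
#'
#' @param items For entity grouping: anything with a length (fold sizes
#'   are over items). For record grouping: a character vector of record
#'   ids, one per item (e.g. `corpus_entities(docs)$doc_id`).
#' @param config A [cv_config()].
#' @return Integer vector of fold ids (1..k), one per item.
#' @export
make_folds <- function(items, config = cv_config()) {
  n <- length(items)
  if (config$grouping == "entity") {
    if (n < config$k)
      stop("make_folds: configuration error: fewer items (", n,
           ") than folds (", config$k, ")")
    set.seed(config$seed)
    ord <- sample.int(n)
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(config$k), n)
    folds
  } else {
    ids <- as.character(items)
    uids <- unique(ids)
    if (length(uids) < config$k)
      stop("make_folds: configuration error: fewer records (",
           length(uids), ") than folds (", config$k, ")")
    set.seed(config$seed)
    ord <- sample.int(length(uids))
    rec_fold <- integer(length(uids))
    rec_fold[ord] <- rep_len(seq_len(config$k), length(uids))
    rec_fold[match(ids, uids)]
  }
}

#' Majority vote of exactly three classifiers
#'
#' Assigns, per entity, the label predicted by at least two of the three
#' classifiers. Input must contain exactly three hard labels per entity;
#' anything else is a validation error naming the entity.
#'
#' @param predictions Prediction data frame (rows from three methods;
#'   columns `doc_id`, `entity_index`, `label`, ...).
#' @return Prediction data frame with `method = "ensemble"` and no
#'   probability.
#' @export
majority_vote <- function(predictions) {
  key <- paste(predictions$doc_id, predictions$entity_index, sep = "\r")
  counts <- table(key)
  bad <- names(counts)[counts != 3L]
  if (length(bad)) {
    parts <- strsplit(bad[1], "\r", fixed = TRUE)[[1]]
    stop("majority_vote: validation error: entity (doc ", parts[1],
         ", index ", parts[2], ") has ", counts[bad[1]],
         " predictions, need exactly 3")
  }
  split_idx <- split(seq_len(nrow(predictions)), key)
  rows <- lapply(split_idx, function(ix) {
    votes <- predictions$label[ix]
    lab <- if (sum(votes == "negated") >= 2L) "negated" else "not_negated"
    data.frame(doc_id = predictions$doc_id[ix[1]],
               entity_index = predictions$entity_index[ix[1]],
               label = lab, probability = NA_real_, method = "ensemble",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$doc_id, out$entity_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision, recall and F1 for the negated class
#'
#' The positive class is *negated*. Precision is `tp / (tp + fp)`,
#' recall is `tp / (tp + fn)`, F1 their harmonic mean. Undefined ratios
#' (zero denominator) are reported as `NA`, never as 0, so they cannot
#' silently deflate or inflate averages.
#'
#' @param predictions Prediction data frame covering every gold entity
#'   exactly once (`doc_id`, `entity_index`, `label`).
#' @param gold Gold data frame as [corpus_entities()] (needs `doc_id`,
#'   `entity_index`, `gold_label`, and `category` when stratifying).
#' @param stratify_by_category Also emit one report per record category.
#' @return Data frame of metric reports: `stratum`, `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(predictions, gold, stratify_by_category = TRUE) {
  gkey <- paste(gold$doc_id, gold$entity_index, sep = "\r")
  pkey <- paste(predictions$doc_id, predictions$entity_index, sep = "\r")
  if (anyDuplicated(pkey))
    stop("compute_metrics: validation error: duplicated prediction for entity (",
         gsub("\r", ", ", pkey[duplicated(pkey)][1]), ")")
  miss <- setdiff(pkey, gkey)
  if (length(miss))
    stop("compute_metrics: validation error: prediction without gold label ",
         "for entity (", gsub("\r", ", ", miss[1]), ")")
  miss <- setdiff(gkey, pkey)
  if (length(miss))
    stop("compute_metrics: validation error: gold entity (",
         gsub("\r", ", ", miss[1]), ") has no prediction")
  pred <- predictions$label[match(gkey, pkey)]
  one <- function(sel, stratum) {
    tp <- sum(sel & pred == "negated" & gold$gold_label == "negated")
    fp <- sum(sel & pred == "negated" & gold$gold_label == "not_negated")
    fn <- sum(sel & pred == "not_negated" & gold$gold_label == "negated")
    tn <- sum(sel & pred == "not_negated" & gold$gold_label == "not_negated")
    precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    data.frame(stratum = stratum, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  }
  out <- one(rep(TRUE, nrow(gold)), "all")
  if (stratify_by_category && "category" %in% names(gold)) {
    for (cat in intersect(record_categories(), unique(gold$category)))
      out <- rbind(out, one(gold$category == cat, cat))
  }
  rownames(out) <- NULL
  out
}

#' Exclusive error-set intersections
#'
#' Given the per-method error sets over a shared entity universe, counts
#' each erred-on entity in exactly the subset of methods that erred on
#' it (the bars of an UpSet-style plot). Counts over all non-empty
#' subsets sum to the size of the union of the error sets.
#'
#' @param error_sets Named list of character vectors (entity keys) of
#'   errors per method.
#' @return Data frame `methods` (method names joined by `"&"`), `count`,
#'   covering every non-empty method subset.
#' @export
error_intersections <- function(error_sets) {
  methods <- names(error_sets)
  stopifnot(!is.null(methods), all(nzchar(methods)))
  universe <- unique(unlist(error_sets))
  membership <- vapply(error_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(methods)))
  subsets <- subsets[rowSums(subsets) > 0L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(subsets)), function(i) {
    mask <- as.logical(subsets[i, ])
    cnt <- if (length(universe))
      sum(apply(membership, 1L, function(r) all(r == mask))) else 0L
    data.frame(methods = paste(methods[mask], collapse = "&"),
               count = cnt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two categorical annotators:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` (the
#' fraction of equal labels) and expected agreement `p_e` (the sum over
#' categories of the marginal products). When `p_e = 1` the statistic is
#' undefined and reported as `NA`. Symmetric in its arguments.
#'
#' @param labels_a,labels_b Equal-length category vectors.
#' @return A `kappa_result`: `list(p_o, p_e, kappa)`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("cohens_kappa: validation error: length mismatch (",
         length(labels_a), " vs ", length(labels_b), ")")
  n <- length(labels_a)
  if (n == 0L) stop("cohens_kappa: empty input")
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  p_o <- mean(labels_a == labels_b)
  cats <- union(labels_a, labels_b)
  pa <- vapply(cats, function(c) mean(labels_a == c), numeric(1))
  pb <- vapply(cats, function(c) mean(labels_b == c), numeric(1))
  p_e <- sum(pa * pb)
  kappa <- if (p_e >= 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("Cohen's kappa: ", signif(x$kappa, 4), " (p_o = ", signif(x$p_o, 4),
      ", p_e = ", signif(x$p_e, 4), ")\n", sep = "")
  invisible(x)
}

#' The error taxonomy
#'
#' The ten categories used when reviewing false positives and false
#' negatives: rare trigger phrasings (`uncommon_negation`), the clinical
#' trailing-hyphen shorthand (`minus`), scope over- or under-reach
#' (`scope`), punctuation hindering splitting (`punctuation`), negation
#' attaching to a nearby different term, hypothetical/historical context
#' (`wrong_modality`), expressed uncertainty (`speculation`), structural
#' `ambiguity`, a catch-all `other`, and gold-label mistakes
#' (`annotation_error`). Categories are assigned by human reviewers; the
#' toolkit validates and tabulates them, never auto-assigns.
#'
#' @return Character vector of the ten category names.
#' @export
error_categories <- function() {
  c("uncommon_negation", "minus", "scope", "punctuation",
    "negation_of_different_term", "wrong_modality", "speculation",
    "ambiguity", "other", "annotation_error")
}

#' Error records and the error-frequency table
#'
#' Turns every false positive (predicted negated, gold not negated) and
#' false negative (the reverse) into an error record listing which
#' methods erred, optionally joined with human-assigned taxonomy
#' categories, plus a frequency table per (method, polarity, category)
#' with percentages of each polarity's total.
#'
#' @param predictions_by_method Named list of prediction data frames,
#'   one per method, each covering the gold entities.
#' @param gold Gold data frame as [corpus_entities()].
#' @param categories Optional data frame `doc_id`, `entity_index`,
#'   `category` (an [error_categories()] value), human-assigned; a
#'   category on a non-error entity is a validation error.
#' @return `list(errors = data.frame(doc_id, entity_index, polarity,
#'   methods, category), frequency = data.frame(method, polarity,
#'   category, n, percent))`.
#' @export
error_report <- function(predictions_by_method, gold, categories = NULL) {
  gkey <- paste(gold$doc_id, gold$entity_index, sep = "\r")
  err_by_method <- lapply(predictions_by_method, function(p) {
    pkey <- paste(p$doc_id, p$entity_index, sep = "\r")
    pred <- p$label[match(gkey, pkey)]
    if (anyNA(pred))
      stop("error_report: validation error: method predictions do not ",
           "cover the gold entities")
    ifelse(pred == "negated" & gold$gold_label == "not_negated",
           "false_positive",
           ifelse(pred == "not_negated" & gold$gold_label == "negated",
                  "false_negative", NA_character_))
  })
  any_err <- Reduce(`|`, lapply(err_by_method, Negate(is.na)))
  idx <- which(any_err)
  errors <- do.call(rbind, lapply(idx, function(i) {
    pol <- stats::na.omit(vapply(err_by_method, `[`, character(1), i))
    data.frame(doc_id = gold$doc_id[i], entity_index = gold$entity_index[i],
               polarity = pol[1],
               methods = paste(names(pol), collapse = "&"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(errors))
    errors <- data.frame(doc_id = character(0), entity_index = integer(0),
                         polarity = character(0), methods = character(0),
                         stringsAsFactors = FALSE)
  errors$category <- rep(NA_character_, nrow(errors))
  if (!is.null(categories) && nrow(categories)) {
    bad <- !categories$category %in% error_categories()
    if (any(bad))
      stop("error_report: unknown error category '",
           categories$category[bad][1], "'")
    ckey <- paste(categories$doc_id, categories$entity_index, sep = "\r")
    ekey <- paste(errors$doc_id, errors$entity_index, sep = "\r")
    orphan <- setdiff(ckey, ekey)
    if (length(orphan))
      stop("error_report: validation error: category assigned to ",
           "non-error entity (", gsub("\r", ", ", orphan[1]), ")")
    errors$category <- categories$category[match(ekey, ckey)]
  }
  # frequency table per (method, polarity, category), % of polarity total
  freq <- list()
  ekey <- paste(errors$doc_id, errors$entity_index, sep = "\r")
  for (m in names(predictions_by_method)) {
    pol <- err_by_method[[m]]
    for (p in c("false_positive", "false_negative")) {
      sel <- which(pol == p)
      total <- length(sel)
      if (!total) next
      cat_of <- errors$category[match(paste(gold$doc_id[sel],
                                            gold$entity_index[sel],
                                            sep = "\r"), ekey)]
      tab <- table(factor(cat_of, levels = error_categories()),
                   useNA = "ifany")
      for (ci in seq_along(tab)) {
        if (tab[[ci]] == 0L) next
        cn <- names(tab)[ci]
        freq[[length(freq) + 1L]] <- data.frame(
          method = m, polarity = p,
          category = if (is.na(cn) || cn == "") NA_character_ else cn,
          n = as.integer(tab[[ci]]),
          percent = 100 * tab[[ci]] / total,
          stringsAsFactors = FALSE)
      }
    }
  }
  frequency <- if (length(freq)) do.call(rbind, freq)
    else data.frame(method = character(0), polarity = character(0),
                    category = character(0), n = integer(0),
                    percent = numeric(0), stringsAsFactors = FALSE)
  rownames(errors) <- rownames(frequency) <- NULL
  list(errors = errors, frequency = frequency)
}

#' Cross-validated evaluation of a training-based method
#'
#' Runs the shared-fold protocol: for each fold, train on the remaining
#' folds and predict the held-out fold; predictions are pooled over all
#' test folds and metrics computed once (micro aggregation), with
#' per-fold metrics kept for variance inspection.
#'
#' @param docs Gold-labeled corpus.
#' @param train_fn `function(train_docs) -> model`.
#' @param predict_fn `function(model, test_docs) -> predictions`.
#' @param config A [cv_config()].
#' @return `list(predictions, metrics, per_fold)`.
#' @export
cross_validate <- function(docs, train_fn, predict_fn,
                           config = cv_config()) {
  gold <- corpus_entities(docs)
  folds <- if (config$grouping == "record") {
    rec_fold <- make_folds(vapply(docs, `[[`, character(1), "doc_id"),
                           cv_config(config$k, config$seed, "record"))
  } else {
    ent_fold <- make_folds(seq_len(nrow(gold)),
                           cv_config(config$k, config$seed, "entity"))
    # entity folds cannot split training at record level; fall back to
    # record assignment of each entity's record for training exclusion
    ent_fold
  }
  preds <- list(); per_fold <- list()
  for (f in seq_len(config$k)) {
    if (config$grouping == "record") {
      test_docs <- docs[folds[seq_along(docs)] == f]
      train_docs <- docs[folds[seq_along(docs)] != f]
    } else {
      test_ids <- unique(gold$doc_id[folds == f])
      test_docs <- docs[vapply(docs, `[[`, character(1), "doc_id") %in% test_ids]
      train_docs <- docs[!vapply(docs, `[[`, character(1), "doc_id") %in% test_ids]
    }
    model <- train_fn(train_docs)
    p <- predict_fn(model, test_docs)
    preds[[f]] <- p
    per_fold[[f]] <- cbind(fold = f,
                           compute_metrics(p, corpus_entities(test_docs),
                                           stratify_by_category = FALSE))
  }
  predictions <- do.call(rbind, preds)
  list(predictions = predictions,
       metrics = compute_metrics(predictions, gold),
       per_fold = do.call(rbind, per_fold))
}
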