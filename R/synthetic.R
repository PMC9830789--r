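# Synthetic clinical-corpus generator with known ground truth. Documents
# are built sentence-by-sentence from a trigger grammar aligned with the
# packaged lexicon, so negation labels are sound by construction (and
# re-derived with a token-level scope oracle at generation time).
# Category realism is statistical only: per-category record length
# targets, a ~14% negated-entity prevalence, and the clinical noise
# phenomena (minus shorthand, missing whitespace, abbreviation periods).

# function words free of any lexicon trigger word
SYN_FUNCTION_WORDS <- c("de", "het", "een", "en", "bij", "met", "na", "op",
                        "in", "aan", "sinds", "tijdens", "patient",
                        "controle", "beloop", "verder", "vandaag", "rustig",
                        "stabiel", "gisteren", "vanmorgen", "nadien")

#' Default synthetic trigger grammar
#'
#' The trigger inventory the generator negates entities with, aligned
#' with [default_lexicon()] so that the rule engine can achieve perfect
#' scores on noise-free output. Weights give each trigger's relative use.
#'
#' @return List with `forward`, `backward` (lists of
#'   `list(tokens, weight)`), `termination` and `pseudo` phrase lists.
#' @export
default_grammar <- function() {
  list(
    forward = list(
      list(tokens = "geen", weight = 0.40),
      list(tokens = c("geen", "aanwijzingen", "voor"), weight = 0.20),
      list(tokens = c("geen", "tekenen", "van"), weight = 0.10),
      list(tokens = "zonder", weight = 0.10)),
    backward = list(
      list(tokens = "uitgesloten", weight = 0.10),
      list(tokens = c("werd", "uitgesloten"), weight = 0.05),
      list(tokens = "afwezig", weight = 0.05)),
    termination = c("maar", "wel"),
    pseudo = list(c("niet", "alleen"))
  )
}

syn_terms <- function() {
  path <- system.file("extdata", "synthetic_terms.txt",
                      package = "negdetect", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

default_length_targets <- function() {
  data.frame(
    category = record_categories(),
    mean_sentences = c(2.1, 3.8, 3.6, 4.1),
    mean_words = c(17.8, 30.0, 19.1, 33.8),
    stringsAsFactors = FALSE)
}

default_category_mix <- function() {
  mix <- c(general_practitioner = 2034, specialist_letter = 2737,
           radiology_report = 3939, discharge_letter = 3057)
  mix / sum(mix)
}

#' Configuration of the synthetic corpus generator
#'
#' Defaults state the emulated world: four record categories mixed by
#' their corpus share, per-category mean sentences/words per record
#' (negative-binomial lengths around the means, over-dispersed like real
#' record lengths), a 14% negated-entity prevalence, a lexicon-aligned
#' trigger grammar, and noise rates (all off by default).
#'
#' @param n_documents Number of records to generate.
#' @param category_mix Named probabilities over [record_categories()].
#' @param negation_prevalence Probability that an entity is negated
#'   (default 0.14).
#' @param grammar Trigger grammar, see [default_grammar()].
#' @param minus_rate,whitespace_rate,punctuation_rate Noise rates in
#'   `[0, 1]`, applied per sentence by [inject_noise()].
#' @param length_targets Data frame `category`, `mean_sentences`,
#'   `mean_words`.
#' @param p_entity,p_second_entity Probability that a sentence carries an
#'   entity / a second entity.
#' @param seed RNG seed; the whole corpus is a deterministic function of
#'   the config.
#' @return A `generator_config`.
#' @export
generator_config <- function(n_documents = 100L,
                             category_mix = default_category_mix(),
                             negation_prevalence = 0.14,
                             grammar = default_grammar(),
                             minus_rate = 0, whitespace_rate = 0,
                             punctuation_rate = 0,
                             length_targets = default_length_targets(),
                             p_entity = 0.65, p_second_entity = 0.2,
                             seed = 42L) {
  problems <- character(0)
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0 | x > 1))
      problems <<- c(problems, paste0(nm, " must lie in [0, 1]"))
  }
  if (!is.numeric(n_documents) || n_documents < 1)
    problems <- c(problems, "n_documents must be >= 1")
  chk01(negation_prevalence, "negation_prevalence")
  chk01(minus_rate, "minus_rate")
  chk01(whitespace_rate, "whitespace_rate")
  chk01(punctuation_rate, "punctuation_rate")
  chk01(p_entity, "p_entity")
  chk01(p_second_entity, "p_second_entity")
  if (!setequal(names(category_mix), record_categories()) ||
      any(category_mix < 0))
    problems <- c(problems,
                  "category_mix must be non-negative over the four categories")
  if (any(length_targets$mean_sentences <= 0) ||
      any(length_targets$mean_words <= 0))
    problems <- c(problems, "length targets must be positive")
  if (length(problems))
    stop("generator_config: configuration error: ",
         paste(problems, collapse = "; "))
  structure(list(n_documents = as.integer(n_documents),
                 category_mix = category_mix[record_categories()] /
                   sum(category_mix),
                 negation_prevalence = negation_prevalence,
                 grammar = grammar, minus_rate = minus_rate,
                 whitespace_rate = whitespace_rate,
                 punctuation_rate = punctuation_rate,
                 length_targets = length_targets,
                 p_entity = p_entity, p_second_entity = p_second_entity,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# token-level scope oracle used to certify generated labels: literal
# phrase matching, pseudo precedence, longest-match-first, termination
# truncation, default sentence scope, no self-negation.
token_scope_labels <- function(tokens, ent_ranges, grammar) {
  toks <- tolower(tokens)
  phrases <- c(
    lapply(grammar$forward, function(g)
      list(tokens = g$tokens, category = "negation_forward")),
    lapply(grammar$backward, function(g)
      list(tokens = g$tokens, category = "negation_backward")),
    lapply(grammar$pseudo, function(p)
      list(tokens = p, category = "pseudo")),
    lapply(grammar$termination, function(t)
      list(tokens = t, category = "termination")))
  cand <- list()
  for (ph in phrases) {
    p <- tolower(ph$tokens); L <- length(p)
    if (L > length(toks)) next
    for (s in seq_len(length(toks) - L + 1L))
      if (all(toks[s:(s + L - 1L)] == p))
        cand[[length(cand) + 1L]] <- list(from = s, to = s + L - 1L,
                                          category = ph$category)
  }
  if (!length(cand)) return(rep("not_negated", length(ent_ranges)))
  # pseudo precedence
  pse <- Filter(function(m) m$category == "pseudo", cand)
  cand <- Filter(function(m) {
    if (!grepl("^negation_", m$category)) return(TRUE)
    !any(vapply(pse, function(q) m$from >= q$from && m$to <= q$to,
                logical(1)))
  }, cand)
  # longest-first greedy overlap resolution
  ord <- order(-vapply(cand, function(m) m$to - m$from, numeric(1)),
               vapply(cand, `[[`, numeric(1), "from"))
  kept <- list()
  for (m in cand[ord]) {
    clash <- any(vapply(kept, function(k) m$from <= k$to && m$to >= k$from,
                        logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- m
  }
  terms <- Filter(function(m) m$category == "termination", kept)
  labels <- rep("not_negated", length(ent_ranges))
  for (m in Filter(function(m) grepl("^negation_", m$category), kept)) {
    if (m$category == "negation_forward") {
      from <- m$to + 1L; to <- length(toks)
      after <- vapply(terms, `[[`, numeric(1), "from")
      after <- after[after > m$to]
      if (length(after)) to <- min(to, min(after) - 1L)
    } else {
      from <- 1L; to <- m$from - 1L
      before <- vapply(terms, `[[`, numeric(1), "to")
      before <- before[before < m$from]
      if (length(before)) from <- max(from, max(before) + 1L)
    }
    if (from > to) next
    for (k in seq_along(ent_ranges)) {
      r <- ent_ranges[[k]]
      if (r[1] <= m$to && r[2] >= m$from) next   # overlaps the trigger
      if (any(seq(r[1], r[2]) >= from & seq(r[1], r[2]) <= to))
        labels[k] <- "negated"
    }
  }
  labels
}

sample_weighted <- function(items) {
  w <- vapply(items, `[[`, numeric(1), "weight")
  items[[sample.int(length(items), 1L, prob = w)]]$tokens
}

# build one sentence: returns list(tokens, ents = list(list(range)),
# trig_tokens = indices of trigger words, labels, mechanisms)
syn_sentence <- function(n_entities, labels, target_words, grammar, terms) {
  filler <- function(n) if (n > 0L) sample(SYN_FUNCTION_WORDS, n,
                                           replace = TRUE) else character(0)
  term1 <- function() {
    w <- sample(terms, 1L)
    strsplit(w, " ", fixed = TRUE)[[1]]
  }
  tokens <- character(0); ents <- list(); trig <- integer(0)
  mechanisms <- character(0)
  add <- function(x) { tokens <<- c(tokens, x); invisible(NULL) }
  add_ent <- function() {
    e <- term1()
    from <- length(tokens) + 1L
    add(e)
    ents[[length(ents) + 1L]] <<- c(from, length(tokens))
  }
  add_trig <- function(tt) {
    from <- length(tokens) + 1L
    add(tt)
    trig <<- c(trig, from:length(tokens))
  }
  pads <- integer(0)  # gap positions (after token i) where fillers are safe

  if (n_entities == 0L) {
    if (stats::runif(1) < 0.05) add(grammar$pseudo[[sample.int(
      length(grammar$pseudo), 1L)]])
    add(filler(2L))
    pads <- length(tokens)
  } else if (n_entities == 1L) {
    if (labels[1] == "not_negated") {
      use_pseudo <- stats::runif(1) < 0.08
      if (use_pseudo) add(grammar$pseudo[[sample.int(
        length(grammar$pseudo), 1L)]])
      add(filler(1L))
      pads <- c(pads, length(tokens))
      add_ent()
      pads <- c(pads, length(tokens))
      mechanisms <- "none"
    } else {
      backward <- stats::runif(1) <
        sum(vapply(grammar$backward, `[[`, numeric(1), "weight")) /
        sum(vapply(c(grammar$forward, grammar$backward), `[[`,
                   numeric(1), "weight"))
      if (backward) {
        tt <- sample_weighted(grammar$backward)
        add_ent()
        add_trig(tt)
        pads <- c(pads, length(tokens))
        mechanisms <- paste0("trigger_backward:", paste(tt, collapse = " "))
      } else {
        tt <- sample_weighted(grammar$forward)
        pads <- c(pads, 0L)
        add_trig(tt)
        add_ent()
        pads <- c(pads, length(tokens))
        mechanisms <- paste0("trigger_forward:", paste(tt, collapse = " "))
      }
    }
  } else {
    l1 <- labels[1]; l2 <- labels[2]
    if (l1 == "negated" && l2 == "not_negated") {
      tt <- sample_weighted(grammar$forward)
      add_trig(tt); add_ent(); add(","); add(sample(grammar$termination, 1L))
      pads <- c(pads, length(tokens))
      add_ent()
      pads <- c(pads, length(tokens))
      mechanisms <- c(paste0("trigger_forward:", paste(tt, collapse = " ")),
                      "none")
    } else if (l1 == "not_negated" && l2 == "negated") {
      add(filler(1L)); add_ent()
      pads <- c(pads, length(tokens))
      tt <- sample_weighted(grammar$forward)
      add_trig(tt); add_ent()
      pads <- c(pads, length(tokens))
      mechanisms <- c("none",
                      paste0("trigger_forward:", paste(tt, collapse = " ")))
    } else if (l1 == "negated" && l2 == "negated") {
      tt <- sample_weighted(grammar$forward)
      add_trig(tt); add_ent(); add("en")
      if (stats::runif(1) < 0.5) {
        add_ent()
        mechanisms <- rep(paste0("trigger_forward:",
                                 paste(tt, collapse = " ")), 2L)
      } else {
        tt2 <- sample_weighted(grammar$forward)
        add_trig(tt2); add_ent()
        mechanisms <- c(paste0("trigger_forward:", paste(tt, collapse = " ")),
                        paste0("trigger_forward:", paste(tt2, collapse = " ")))
      }
      pads <- c(pads, length(tokens))
    } else {
      add(filler(1L))
      pads <- c(pads, length(tokens) - 1L)
      add_ent(); add("en"); add_ent()
      pads <- c(pads, length(tokens))
      mechanisms <- c("none", "none")
    }
  }

  # pad with fillers at safe gaps up to the target word count
  n_words <- sum(is_word_token(tokens))
  need <- target_words - n_words
  if (need > 0L && length(pads)) {
    at <- sample(pads, need, replace = TRUE)
    for (gap in sort(at, decreasing = TRUE)) {
      w <- sample(SYN_FUNCTION_WORDS, 1L)
      tokens <- append(tokens, w, after = gap)
      bump <- function(r) r + (r > gap)
      ents <- lapply(ents, function(r)
        c(r[1] + (r[1] > gap), r[2] + (r[2] > gap)))
      trig <- trig + (trig > gap)
    }
  }
  list(tokens = tokens, ents = ents, trig = trig,
       labels = labels, mechanisms = mechanisms)
}

glue_left <- function(tok) tok %in% c(",", ".", "-")

assemble_doc <- function(struct) {
  text <- ""
  ent_rows <- list()
  for (si in seq_along(struct$sentences)) {
    s <- struct$sentences[[si]]
    if (si > 1L) text <- paste0(text, struct$sep[si - 1L])
    starts <- integer(length(s$tokens)); ends <- integer(length(s$tokens))
    for (ti in seq_along(s$tokens)) {
      if (ti > 1L && !glue_left(s$tokens[ti])) text <- paste0(text, " ")
      starts[ti] <- nchar(text)
      text <- paste0(text, s$tokens[ti])
      ends[ti] <- nchar(text)
    }
    for (k in seq_along(s$ents)) {
      r <- s$ents[[k]]
      ent_rows[[length(ent_rows) + 1L]] <- list(
        start = starts[r[1]], end = ends[r[2]],
        label = s$labels[k], mechanism = s$mechanisms[k])
    }
  }
  ents <- lapply(ent_rows, function(e)
    entity_annotation(e$start, e$end,
                      substr(text, e$start + 1L, e$end),
                      gold_label = e$label))
  doc <- annotated_document(struct$doc_id, text, struct$category, ents)
  list(doc = doc, mechanisms = vapply(ent_rows, `[[`, character(1),
                                      "mechanism"))
}

#' Generate a synthetic labeled corpus
#'
#' Builds records sentence-by-sentence: each sentence may carry one or
#' two entities; each entity is independently negated with the
#' configured prevalence, realized through the trigger grammar (forward
#' trigger before, backward trigger after, shared scopes, termination
#' triggers between mixed-label pairs, occasional pseudo-triggers in
#' non-negated sentences). Generated labels are certified at generation
#' time by a token-level scope oracle, so on noise-free output the
#' labels *are* the scope semantics. Sentence lengths and counts follow
#' negative-binomial distributions around the per-category targets.
#' Reproducible: the corpus is a deterministic function of the config.
#'
#' @param config A [generator_config()].
#' @return `list(corpus, traces)`: the corpus (also carrying `traces`
#'   and the internal generation structure as attributes, which
#'   [inject_noise()] needs) and a data frame with one row per entity
#'   (`doc_id`, `entity_index`, `label`, `mechanism`, `noise`).
#' @export
generate_corpus <- function(config = generator_config()) {
  set.seed(config$seed)
  terms <- syn_terms()
  lt <- config$length_targets
  structs <- vector("list", config$n_documents)
  for (i in seq_len(config$n_documents)) {
    category <- sample(names(config$category_mix), 1L,
                       prob = config$category_mix)
    row <- lt[lt$category == category, ]
    n_sent <- 1L + stats::rnbinom(1L, size = 4,
                                  mu = max(row$mean_sentences - 1, 0.1))
    wps <- row$mean_words / row$mean_sentences
    sentences <- vector("list", n_sent)
    for (si in seq_len(n_sent)) {
      has_ent <- stats::runif(1) < config$p_entity
      n_ent <- if (!has_ent) 0L
               else 1L + (stats::runif(1) < config$p_second_entity)
      labels <- if (n_ent > 0L)
        ifelse(stats::runif(n_ent) < config$negation_prevalence,
               "negated", "not_negated") else character(0)
      target <- max(3L, stats::rnbinom(1L, size = 8, mu = max(wps, 1)))
      s <- syn_sentence(n_ent, labels, target, config$grammar, terms)
      # certify labels against the literal scope semantics
      if (length(s$ents) && length(s$trig)) {
        check <- token_scope_labels(s$tokens, s$ents, config$grammar)
        if (!identical(check, s$labels))
          stop("generate_corpus: internal label soundness failure")
      }
      if (stats::runif(1) < 0.85) s$tokens <- c(s$tokens, ".")
      sentences[[si]] <- s
    }
    sep <- vapply(seq_len(max(n_sent - 1L, 0L)), function(j) {
      s <- sentences[[j]]
      if (s$tokens[length(s$tokens)] == "." && stats::runif(1) < 0.8) " "
      else "\n"
    }, character(1))
    structs[[i]] <- list(doc_id = sprintf("doc_%05d", i),
                         category = category, sentences = sentences,
                         sep = sep)
  }
  corpus <- build_from_structs(structs)
  rates <- list(minus = config$minus_rate,
                whitespace = config$whitespace_rate,
                punctuation = config$punctuation_rate)
  if (any(unlist(rates) > 0))
    corpus <- inject_noise(corpus, rates, seed = config$seed + 1L)
  list(corpus = corpus, traces = attr(corpus, "traces"))
}

build_from_structs <- function(structs, noise = NULL) {
  docs <- vector("list", length(structs))
  trace_rows <- list()
  for (i in seq_along(structs)) {
    a <- assemble_doc(structs[[i]])
    docs[[i]] <- a$doc
    n <- length(a$doc$entities)
    if (n) {
      key <- paste0(structs[[i]]$doc_id, "\r", seq_len(n))
      trace_rows[[length(trace_rows) + 1L]] <- data.frame(
        doc_id = structs[[i]]$doc_id, entity_index = seq_len(n),
        label = vapply(a$doc$entities, `[[`, character(1), "gold_label"),
        mechanism = a$mechanisms,
        noise = if (is.null(noise)) "" else noise[key],
        stringsAsFactors = FALSE)
    }
  }
  traces <- do.call(rbind, trace_rows)
  if (is.null(traces))
    traces <- data.frame(doc_id = character(0), entity_index = integer(0),
                         label = character(0), mechanism = character(0),
                         noise = character(0), stringsAsFactors = FALSE)
  rownames(traces) <- NULL
  corpus <- as_corpus(docs)
  attr(corpus, "traces") <- traces
  attr(corpus, "gen_structure") <- structs
  corpus
}

#' Inject clinical text noise into a generated corpus
#'
#' Applies, per sentence at the given rates: minus-shorthand conversion
#' (negation triggers removed, a trailing `-` glued to each entity they
#' negated — the label stays *negated*, the mechanism becomes `minus`),
#' whitespace deletion (two adjacent filler words merged), and
#' abbreviation periods (a filler word truncated to four characters plus
#' `.`, sabotaging sentence splitting). Entity offsets are recomputed
#' and remain valid; the traces are updated. Needs the generation
#' structure attribute, i.e. a corpus from [generate_corpus()].
#'
#' @param corpus Generated corpus (with `gen_structure` attribute).
#' @param rates List with any of `minus`, `whitespace`, `punctuation`,
#'   each in `[0, 1]`.
#' @param seed RNG seed.
#' @return The noisy corpus, with updated `traces` and `gen_structure`
#'   attributes.
#' @export
inject_noise <- function(corpus, rates = list(), seed = 1L) {
  rates <- utils::modifyList(list(minus = 0, whitespace = 0,
                                  punctuation = 0), rates)
  if (any(unlist(rates) < 0 | unlist(rates) > 1))
    stop("inject_noise: rates must lie in [0, 1]")
  structs <- attr(corpus, "gen_structure")
  if (is.null(structs))
    stop("inject_noise: corpus lacks the generation structure ",
         "(only corpora from generate_corpus can be noised)")
  set.seed(seed)
  noise <- character(0)
  for (i in seq_along(structs)) {
    ent_counter <- 0L
    for (si in seq_along(structs[[i]]$sentences)) {
      s <- structs[[i]]$sentences[[si]]
      n_ent_here <- length(s$ents)
      ent_ids <- if (n_ent_here) ent_counter + seq_len(n_ent_here)
                 else integer(0)
      ent_counter <- ent_counter + n_ent_here
      applied <- character(n_ent_here)

      if (rates$minus > 0 && length(s$trig) &&
          any(s$labels == "negated") && stats::runif(1) < rates$minus) {
        neg <- which(s$labels == "negated" &
                       startsWith(s$mechanisms, "trigger"))
        if (length(neg)) {
          drop <- sort(s$trig)
          # glue a "-" after each negated entity's last token
          keep <- setdiff(seq_along(s$tokens), drop)
          remap <- match(seq_along(s$tokens), keep)
          new_tokens <- s$tokens[keep]
          new_ents <- lapply(s$ents, function(r)
            c(remap[r[1]], remap[r[2]]))
          for (k in rev(neg)) {
            after <- new_ents[[k]][2]
            new_tokens <- append(new_tokens, "-", after = after)
            new_ents <- lapply(seq_along(new_ents), function(j) {
              r <- new_ents[[j]]
              c(r[1] + (r[1] > after), r[2] + (r[2] > after))
            })
          }
          s$tokens <- new_tokens; s$ents <- new_ents; s$trig <- integer(0)
          s$mechanisms[neg] <- "minus"
          applied[neg] <- "minus"
        }
      }
      protected <- function() {
        p <- unlist(lapply(s$ents, function(r) seq(r[1], r[2])))
        c(p, s$trig)
      }
      if (rates$whitespace > 0 && stats::runif(1) < rates$whitespace) {
        words <- which(is_word_token(s$tokens))
        cand <- words[(words + 1L) %in% words &
                        !words %in% protected() &
                        !(words + 1L) %in% protected()]
        if (length(cand)) {
          j <- if (length(cand) == 1L) cand else sample(cand, 1L)
          s$tokens[j] <- paste0(s$tokens[j], s$tokens[j + 1L])
          s$tokens <- s$tokens[-(j + 1L)]
          s$ents <- lapply(s$ents, function(r)
            c(r[1] - (r[1] > j), r[2] - (r[2] > j)))
          s$trig <- s$trig - (s$trig > j)
          applied[applied == ""] <- "whitespace"
        }
      }
      if (rates$punctuation > 0 && stats::runif(1) < rates$punctuation) {
        cand <- which(is_word_token(s$tokens) & nchar(s$tokens) >= 5L &
                        !seq_along(s$tokens) %in% protected())
        if (length(cand)) {
          j <- if (length(cand) == 1L) cand else sample(cand, 1L)
          s$tokens[j] <- paste0(substr(s$tokens[j], 1L, 4L), ".")
          applied[applied == ""] <- "punctuation"
        }
      }
      structs[[i]]$sentences[[si]] <- s
      if (n_ent_here)
        noise[paste0(structs[[i]]$doc_id, "\r", ent_ids)] <- applied
    }
  }
  build_from_structs(structs, noise = noise)
}
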