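#' Record categories
#'
#' The four clinical record categories the toolkit distinguishes. Category
#' membership drives per-stratum evaluation and the synthetic generator's
#' length targets.
#'
#' @return Character vector of the four category names.
#' @export
record_categories <- function() {
  c("general_practitioner", "specialist_letter",
    "radiology_report", "discharge_letter")
}

#' Negation labels
#'
#' The binary label set: a term is either `negated` or `not_negated`;
#' there is no third value.
#'
#' @return Character vector of length 2.
#' @export
negation_labels <- function() c("negated", "not_negated")

#' Create an entity annotation
#'
#' One annotated medical term: a character span into the document text,
#' its surface form, and an optional gold negation label. Offsets are
#' 0-based, half-open.
#'
#' @param start,end Character offsets, `0 <= start < end`.
#' @param surface Surface string; must equal the text slice `[start, end)`
#'   of the owning document (checked by [annotated_document()]).
#' @param gold_label Optional `"negated"` / `"not_negated"`.
#' @param single_term Dialect flag: `FALSE` marks an annotation that does
#'   not correspond to a single medical term (excluded by
#'   [filter_corpus()]).
#' @return An `entity_annotation` object.
#' @export
entity_annotation <- function(start, end, surface, gold_label = NULL,
                              single_term = TRUE) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("entity_annotation: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!is.null(gold_label) && !gold_label %in% negation_labels())
    stop("entity_annotation: unknown gold_label '", gold_label, "'")
  structure(list(start = start, end = end, surface = as.character(surface),
                 gold_label = gold_label, single_term = isTRUE(single_term)),
            class = "entity_annotation")
}

#' Create an annotated document
#'
#' One clinical record: text, category, and an ordered list of entity
#' annotations. Enforces the span invariants (spans inside the text,
#' surfaces equal to their slice, entities sorted by start offset).
#'
#' @param doc_id Opaque identifier string.
#' @param text Document text, taken verbatim (no unicode normalization, so
#'   offsets stay valid).
#' @param category One of [record_categories()].
#' @param entities List of [entity_annotation()] objects.
#' @param corrupt Flag set by [load_corpus()] on parse failure; corrupt
#'   documents are excluded (with a count) by [filter_corpus()].
#' @return An `annotated_document`.
#' @export
annotated_document <- function(doc_id, text, category, entities = list(),
                               corrupt = FALSE) {
  if (!category %in% record_categories())
    stop("annotated_document: unknown category '", category, "' (doc ", doc_id, ")")
  n <- nchar(text)
  for (e in entities) {
    if (!inherits(e, "entity_annotation"))
      stop("annotated_document: entities must be entity_annotation objects (doc ",
           doc_id, ")")
    if (e$end > n)
      stop("annotated_document: span [", e$start, ", ", e$end,
           ") outside text of length ", n, " (doc ", doc_id, ")")
    slice <- substr(text, e$start + 1L, e$end)
    if (!identical(slice, e$surface))
      stop("annotated_document: surface '", e$surface,
           "' does not match text slice '", slice, "' (doc ", doc_id, ")")
  }
  if (length(entities) > 1L) {
    starts <- vapply(entities, `[[`, integer(1), "start")
    entities <- entities[order(starts)]
  }
  structure(list(doc_id = as.character(doc_id), text = text,
                 category = category, entities = entities,
                 corrupt = isTRUE(corrupt)),
            class = "annotated_document")
}

#' @export
print.annotated_document <- function(x, ...) {
  cat("<annotated_document ", x$doc_id, "> ", x$category, ", ",
      nchar(x$text), " chars, ", length(x$entities), " entities",
      if (x$corrupt) " [corrupt]", "\n", sep = "")
  invisible(x)
}

as_corpus <- function(docs) structure(docs, class = "annotated_corpus")

#' @export
print.annotated_corpus <- function(x, ...) {
  cat("<annotated_corpus> ", length(x), " documents, ",
      sum(vapply(x, function(d) length(d$entities), integer(1))),
      " entities\n", sep = "")
  invisible(x)
}

doc_to_list <- function(doc) {
  ents <- lapply(doc$entities, function(e) {
    out <- list(start = e$start, end = e$end, surface = e$surface)
    if (!is.null(e$gold_label)) out$gold_label <- e$gold_label
    if (!e$single_term) out$single_term <- FALSE
    out
  })
  list(doc_id = doc$doc_id, category = doc$category, text = doc$text,
       entities = ents)
}

doc_from_list <- function(x) {
  ents <- lapply(x$entities, function(e) {
    entity_annotation(e$start, e$end, e$surface,
                      gold_label = e$gold_label,
                      single_term = if (is.null(e$single_term)) TRUE else e$single_term)
  })
  annotated_document(x$doc_id, x$text, x$category, ents)
}

#' Load a corpus from disk
#'
#' Reads a corpus in one of two standoff dialects. The native dialect is
#' JSON-lines: one object per line with fields `doc_id`, `category`,
#' `text`, `entities` (each entity `start`, `end`, `surface`, optional
#' `gold_label`, optional `single_term`). The second dialect is a
#' brat-like two-file layout: a directory with `<id>.txt` plus `<id>.ann`
#' containing tab-separated `T<k>\tTERM <start> <end>\t<surface>` span
#' lines, optional `A<k>\tNegated T<j>` attribute lines and a
#' `#category\t<cat>` comment.
#'
#' Lines/files that fail to parse are *not* silently dropped: a corrupt
#' stub document is kept (flagged `corrupt = TRUE`) and listed in the
#' `problems` attribute, so [filter_corpus()] can count them. A span that
#' parses but violates the document invariants raises a validation error
#' naming the document.
#'
#' @param path File (jsonl) or directory (brat).
#' @param format `"jsonl"` or `"brat"`.
#' @return An `annotated_corpus` (list of documents) with attribute
#'   `problems`: a character vector describing parse failures.
#' @export
load_corpus <- function(path, format = c("jsonl", "brat")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("load_corpus: no such path: ", path)
  if (format == "jsonl") load_corpus_jsonl(path) else load_corpus_brat(path)
}

load_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  problems <- character(0)
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parsed <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) e)
    if (inherits(parsed, "error")) {
      problems <- c(problems,
                    sprintf("line %d: %s", i, conditionMessage(parsed)))
      docs[[i]] <- annotated_document(sprintf("corrupt_line_%d", i), "",
                                      "general_practitioner", corrupt = TRUE)
      next
    }
    docs[[i]] <- doc_from_list(parsed)  # invariant violations propagate
  }
  structure(as_corpus(docs), problems = problems)
}

load_corpus_brat <- function(path) {
  if (!dir.exists(path)) stop("load_corpus: brat dialect needs a directory: ", path)
  txts <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  problems <- character(0)
  docs <- list()
  for (txt in txts) {
    id <- sub("\\.txt$", "", basename(txt))
    ann <- file.path(path, paste0(id, ".ann"))
    text <- paste(readLines(txt, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
    category <- "general_practitioner"
    ents <- list(); labels <- character(0)
    ok <- TRUE
    if (file.exists(ann)) {
      for (line in readLines(ann, encoding = "UTF-8", warn = FALSE)) {
        if (!nzchar(trimws(line))) next
        fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
        if (startsWith(fields[1], "#category")) {
          category <- trimws(fields[2])
        } else if (grepl("^T", fields[1])) {
          spec <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
          if (length(spec) != 3L || length(fields) < 3L) {
            problems <- c(problems, sprintf("%s: bad span line '%s'", id, line))
            ok <- FALSE
            next
          }
          ents[[fields[1]]] <- entity_annotation(
            as.integer(spec[2]), as.integer(spec[3]), fields[3])
        } else if (grepl("^A", fields[1])) {
          spec <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
          labels[spec[2]] <- if (spec[1] == "Negated") "negated"
                             else "not_negated"
        }
      }
    }
    for (tid in intersect(names(ents), names(labels)))
      ents[[tid]]$gold_label <- labels[[tid]]
    docs[[length(docs) + 1L]] <-
      annotated_document(id, text, category, unname(ents), corrupt = !ok)
  }
  structure(as_corpus(docs), problems = problems)
}

#' Save a corpus to disk
#'
#' Writes the dialects read by [load_corpus()]. Writing is deterministic:
#' the same corpus always produces byte-identical output, and
#' `load_corpus(save_corpus(x))` is structurally the identity on valid
#' corpora.
#'
#' @param docs An `annotated_corpus` or plain list of documents.
#' @param path Output file (jsonl) or directory (brat; created).
#' @param format `"jsonl"` or `"brat"`.
#' @return `path`, invisibly.
#' @export
save_corpus <- function(docs, path, format = c("jsonl", "brat")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(docs, function(d) {
      as.character(jsonlite::toJSON(doc_to_list(d), auto_unbox = TRUE,
                                    digits = NA))
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, useBytes = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (d in docs) {
      writeLines(d$text, file.path(path, paste0(d$doc_id, ".txt")),
                 useBytes = FALSE)
      lines <- paste0("#category\t", d$category)
      a <- 0L
      for (i in seq_along(d$entities)) {
        e <- d$entities[[i]]
        lines <- c(lines, sprintf("T%d\tTERM %d %d\t%s", i, e$start, e$end,
                                  e$surface))
        if (!is.null(e$gold_label)) {
          a <- a + 1L
          lines <- c(lines, sprintf("A%d\t%s T%d", a,
                                    if (e$gold_label == "negated") "Negated"
                                    else "NotNegated", i))
        }
      }
      writeLines(lines, file.path(path, paste0(d$doc_id, ".ann")),
                 useBytes = FALSE)
    }
  }
  invisible(path)
}

#' Apply the record-exclusion filters
#'
#' Drops, with per-reason counts, exactly the three record classes that
#' the corpus-loading stage excludes from analysis: records without any
#' annotation, records flagged corrupt by the loader, and records whose
#' annotation does not correspond to a single medical term (the dialect's
#' `single_term = FALSE` flag). Filtering is total (never errors) and
#' conserves counts: `length(kept) + sum(exclusion_log) == length(docs)`.
#'
#' @param docs An `annotated_corpus` or list of documents.
#' @return `list(kept = corpus, exclusion_log = named integer vector)`;
#'   the log only lists reasons that occurred.
#' @export
filter_corpus <- function(docs) {
  reasons <- vapply(docs, function(d) {
    if (isTRUE(d$corrupt)) return("corrupted")
    if (length(d$entities) == 0L) return("no_annotation")
    if (any(!vapply(d$entities, `[[`, logical(1), "single_term")))
      return("not_single_term")
    ""
  }, character(1))
  kept <- as_corpus(docs[reasons == ""])
  log <- table(reasons[reasons != ""])
  exclusion_log <- stats::setNames(as.integer(log), names(log))
  list(kept = kept, exclusion_log = exclusion_log)
}

#' Entities of a corpus as a data frame
#'
#' Convenience flattening used throughout evaluation: one row per entity
#' with document id, 1-based entity index, span, surface, gold label and
#' record category.
#'
#' @param docs An `annotated_corpus` or list of documents.
#' @return A data frame with columns `doc_id`, `entity_index`, `start`,
#'   `end`, `surface`, `gold_label`, `category`.
#' @export
corpus_entities <- function(docs) {
  rows <- lapply(docs, function(d) {
    if (!length(d$entities)) return(NULL)
    data.frame(
      doc_id = d$doc_id,
      entity_index = seq_along(d$entities),
      start = vapply(d$entities, `[[`, integer(1), "start"),
      end = vapply(d$entities, `[[`, integer(1), "end"),
      surface = vapply(d$entities, `[[`, character(1), "surface"),
      gold_label = vapply(d$entities, function(e)
        if (is.null(e$gold_label)) NA_character_ else e$gold_label,
        character(1)),
      category = d$category,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(0), entity_index = integer(0),
                      start = integer(0), end = integer(0),
                      surface = character(0), gold_label = character(0),
                      category = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Entities exceeding a method's sequence limit
#'
#' Some methods impose a maximum record length in tokens; entities in
#' records longer than the limit cannot be scored by them. This is a
#' per-method capability mask, not a corpus-level filter: callers decide
#' whether to drop the masked entities from all methods' evaluation (as
#' when comparing methods on an identical entity set) or only from the
#' limited method.
#'
#' @param docs Corpus.
#' @param limit A [sequence_limit()] or integer maximum token count.
#' @return Data frame (`doc_id`, `entity_index`) of masked entities, with
#'   attribute `n_overlength_docs`.
#' @export
overlength_entities <- function(docs, limit = sequence_limit()) {
  max_len <- if (is.list(limit)) limit$max_sequence_length else as.integer(limit)
  rows <- lapply(docs, function(d) {
    ntok <- nrow(tokenize_spans(d$text))
    if (ntok <= max_len || !length(d$entities)) return(NULL)
    data.frame(doc_id = d$doc_id, entity_index = seq_along(d$entities),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(0), entity_index = integer(0),
                      stringsAsFactors = FALSE)
  attr(out, "n_overlength_docs") <- length(unique(out$doc_id))
  out
}
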