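# Prediction-file I/O (shared JSON-lines schema) and classifier
# persistence as a plain-text model directory.

#' Write predictions as JSON lines
#'
#' One object per line: `doc_id`, `entity_index`, `label`,
#' `probability` (omitted when absent), `method`. Writing is atomic
#' (temp file + rename) and deterministic.
#'
#' @param predictions Prediction data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  lines <- vapply(seq_len(nrow(predictions)), function(i) {
    row <- list(doc_id = predictions$doc_id[i],
                entity_index = predictions$entity_index[i],
                label = predictions$label[i])
    if (!is.na(predictions$probability[i]))
      row$probability <- predictions$probability[i]
    row$method <- predictions$method[i]
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA))
  }, character(1))
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(lines, con)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read predictions from JSON lines
#'
#' @param path File written by [write_predictions()].
#' @return Prediction data frame.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    data.frame(doc_id = x$doc_id, entity_index = as.integer(x$entity_index),
               label = x$label,
               probability = if (is.null(x$probability)) NA_real_
                             else as.numeric(x$probability),
               method = x$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(0), entity_index = integer(0),
                      label = character(0), probability = numeric(0),
                      method = character(0), stringsAsFactors = FALSE)
  out
}

write_matrix <- function(m, path) {
  con <- file(path, open = "wb")
  writeLines(c(paste(dim(m), collapse = " "),
               vapply(seq_len(nrow(m)), function(i)
                 paste(format(m[i, ], digits = 17, scientific = TRUE,
                              trim = TRUE), collapse = " "),
                 character(1))), con)
  close(con)
}

read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  d <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  vals <- lapply(lines[-1], function(l)
    as.numeric(strsplit(l, " ", fixed = TRUE)[[1]]))
  matrix(unlist(vals), nrow = d[1], ncol = d[2], byrow = TRUE)
}

#' Persist a trained classifier as a plain-text model directory
#'
#' Layout: `manifest.json` (versioned: hyperparameters, vocabulary,
#' threshold, window config, loss history, BPE alphabet and merge
#' rules), one text matrix file per weight block, and `biases.json`.
#' [load_classifier()] restores an identical model.
#'
#' @param classifier A `context_classifier`.
#' @param dir Target directory (created).
#' @return `dir`, invisibly.
#' @export
save_classifier <- function(classifier, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    schema = "negdetect-bilstm", version = 1L,
    vocab = classifier$vocab,
    hyperparams = classifier$hyperparams,
    threshold = classifier$threshold,
    loss_history = classifier$loss_history,
    window = if (is.null(classifier$window)) NULL else
      unclass(classifier$window),
    # JSON strings survive whitespace symbols in the alphabet; a raw
    # merges.txt would not
    tokenizer = if (is.null(classifier$tokenizer)) NULL else
      list(alphabet = classifier$tokenizer$alphabet,
           merges = classifier$tokenizer$merges))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p <- classifier$params
  for (nm in c("emb", "fWx", "fWh", "bWx", "bWh", "W1", "W2"))
    write_matrix(p[[nm]], file.path(dir, paste0(nm, ".mat")))
  vecs <- list(fb = p$fb, bb = p$bb, b1 = p$b1, b2 = p$b2)
  jsonlite::write_json(vecs, file.path(dir, "biases.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  params <- list()
  for (nm in c("emb", "fWx", "fWh", "bWx", "bWh", "W1", "W2"))
    params[[nm]] <- read_matrix(file.path(dir, paste0(nm, ".mat")))
  biases <- jsonlite::fromJSON(file.path(dir, "biases.json"),
                               simplifyVector = TRUE)
  params$fb <- as.numeric(biases$fb); params$bb <- as.numeric(biases$bb)
  params$b1 <- as.numeric(biases$b1); params$b2 <- as.numeric(biases$b2)
  tokenizer <- NULL
  if (!is.null(manifest$tokenizer)) {
    alphabet <- as.character(manifest$tokenizer$alphabet)
    merges <- as.character(manifest$tokenizer$merges)
    vocab <- c(alphabet,
               vapply(merges, function(m)
                 paste(strsplit(m, "\r", fixed = TRUE)[[1]], collapse = ""),
                 character(1), USE.NAMES = FALSE))
    tokenizer <- structure(list(alphabet = alphabet, merges = merges,
                                vocab = vocab), class = "bpe_tokenizer")
  }
  window <- NULL
  if (!is.null(manifest$window))
    window <- window_config(manifest$window$left_tokens,
                            manifest$window$right_tokens,
                            manifest$window$placeholder_symbol)
  structure(list(vocab = manifest$vocab, params = params,
                 hyperparams = manifest$hyperparams,
                 loss_history = manifest$loss_history,
                 tokenizer = tokenizer, window = window,
                 threshold = manifest$threshold),
            class = "context_classifier")
}
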