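# Byte-pair-encoding subword tokenizer, trained from scratch. Merges are
# learned greedily by descending pair frequency; ties break
# lexicographically on the pair so training is deterministic. Whitespace
# characters are their own symbols and are never merged, which makes
# detokenization (plain concatenation) the exact inverse of tokenization.

#' Train a byte-pair-encoding tokenizer
#'
#' Starts from the corpus' character alphabet and greedily merges the
#' most frequent adjacent symbol pair (within words; never across
#' whitespace) until `vocab_size` symbols exist or no pair occurs twice.
#' Equal frequencies break lexicographically, so training is
#' deterministic.
#'
#' @param texts Non-empty character vector of training text.
#' @param vocab_size Target vocabulary size; must be at least the
#'   alphabet size.
#' @return A `bpe_tokenizer`: base alphabet, ordered merge rules, and the
#'   token vocabulary.
#' @export
train_bpe <- function(texts, vocab_size) {
  texts <- texts[nzchar(texts)]
  if (!length(texts)) stop("train_bpe: empty corpus")
  alphabet <- sort(unique(unlist(strsplit(texts, "", fixed = TRUE))),
                   method = "radix")
  vocab_size <- as.integer(vocab_size)
  if (vocab_size < length(alphabet))
    stop("train_bpe: configuration error: vocab_size (", vocab_size,
         ") < alphabet size (", length(alphabet), ")")

  words <- unlist(strsplit(texts, "\\s+", perl = TRUE))
  words <- words[nzchar(words)]
  wf <- table(words)
  seqs <- strsplit(names(wf), "", fixed = TRUE)
  freq <- as.integer(wf)

  merges <- character(0)   # "a\rb" encoded pairs, in learned order
  vocab <- alphabet
  while (length(vocab) < vocab_size) {
    # count adjacent pairs weighted by word frequency
    counts <- new.env(parent = emptyenv())
    for (k in seq_along(seqs)) {
      s <- seqs[[k]]
      if (length(s) < 2L) next
      pairs <- paste(s[-length(s)], s[-1L], sep = "\r")
      for (p in unique(pairs)) {
        prev <- if (is.null(counts[[p]])) 0L else counts[[p]]
        counts[[p]] <- prev + sum(pairs == p) * freq[k]
      }
    }
    keys <- ls(counts)
    if (!length(keys)) break
    vals <- vapply(keys, function(k) counts[[k]], integer(1))
    best_n <- max(vals)
    if (best_n < 2L) break
    best <- sort(keys[vals == best_n], method = "radix")[1L]
    ab <- strsplit(best, "\r", fixed = TRUE)[[1]]
    merged <- paste0(ab[1], ab[2])
    merges <- c(merges, best)
    vocab <- c(vocab, merged)
    seqs <- lapply(seqs, apply_merge, a = ab[1], b = ab[2], ab = merged)
  }
  structure(list(alphabet = alphabet, merges = merges, vocab = vocab),
            class = "bpe_tokenizer")
}

apply_merge <- function(s, a, b, ab) {
  n <- length(s)
  if (n < 2L) return(s)
  hit <- which(s[-n] == a & s[-1L] == b)
  if (!length(hit)) return(s)
  # consecutive overlapping hits (e.g. "aaa" with a+a): keep leftmost-first
  keep <- hit[c(TRUE, diff(hit) > 1L)]
  drop <- logical(n)
  s[keep] <- ab
  drop[keep + 1L] <- TRUE
  # re-run in case dropping created new adjacency of the same pair
  s <- s[!drop]
  if (any(s[-length(s)] == a & s[-1L] == b)) apply_merge(s, a, b, ab) else s
}

#' @export
print.bpe_tokenizer <- function(x, ...) {
  cat("<bpe_tokenizer> alphabet ", length(x$alphabet), ", merges ",
      length(x$merges), ", vocab ", length(x$vocab), "\n", sep = "")
  invisible(x)
}

#' Tokenize text with a trained BPE tokenizer
#'
#' Splits the text into characters and applies the learned merges in
#' order. Whitespace characters come through as single-character tokens,
#' so `paste0` over the result reconstructs the input exactly (see
#' [bpe_decode()]). Characters outside the training alphabet come
#' through as single-character tokens too (they map to the reserved
#' unknown id downstream) — tokenization never fails.
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param text String to tokenize.
#' @return Character vector of subword tokens.
#' @export
bpe_encode <- function(tokenizer, text) {
  if (!nzchar(text)) return(character(0))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_ws <- grepl("^\\s$", chars)
  # segment into alternating whitespace / word runs, merge within words
  seg_id <- cumsum(c(TRUE, is_ws[-1L] | is_ws[-length(is_ws)]))
  out <- character(0)
  for (seg in split(seq_along(chars), seg_id)) {
    if (is_ws[seg[1L]]) { out <- c(out, chars[seg]); next }
    s <- chars[seg]
    for (m in tokenizer$merges) {
      ab <- strsplit(m, "\r", fixed = TRUE)[[1]]
      s <- apply_merge(s, ab[1], ab[2], paste0(ab[1], ab[2]))
      if (length(s) == 1L) break
    }
    out <- c(out, s)
  }
  out
}

#' Reassemble BPE tokens into text
#'
#' Exact inverse of [bpe_encode()]: plain concatenation.
#'
#' @param tokens Character vector of subword tokens.
#' @return The reconstructed string.
#' @export
bpe_decode <- function(tokens) paste(tokens, collapse = "")

#' Map subword tokens to vocabulary ids
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param tokens Character vector of subword tokens.
#' @return Integer ids into `tokenizer$vocab`; out-of-vocabulary tokens
#'   are `NA` (callers map them to a reserved unknown id).
#' @export
bpe_token_ids <- function(tokenizer, tokens) {
  match(tokens, tokenizer$vocab)
}
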