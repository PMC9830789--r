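# Word-level tokenization and rule-based sentence splitting shared by the
# rule engine, the window builders and the synthetic generator.

WORD_RX <- "[\\p{L}\\p{N}]+-|[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]"
WORD_RX_SPLIT_MINUS <- "[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]"

#' Tokenize text into word-level spans
#'
#' Tokens are maximal runs of letters/digits, with each punctuation mark
#' its own token. A hyphen directly trailing a word stays attached to it
#' (`"koorts-"` is one token) so that the clinical minus-shorthand
#' survives tokenization; `split_minus = TRUE` is the preprocessing
#' variant that detaches it.
#'
#' @param text String to tokenize.
#' @param split_minus Detach trailing hyphens into their own tokens.
#' @return Data frame with columns `start`, `end` (0-based half-open
#'   character offsets into `text`) and `token`.
#' @export
tokenize_spans <- function(text, split_minus = FALSE) {
  rx <- if (split_minus) WORD_RX_SPLIT_MINUS else WORD_RX
  empty <- data.frame(start = integer(0), end = integer(0),
                      token = character(0), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + len,
             token = substring(text, m, m + len - 1L),
             stringsAsFactors = FALSE)
}

#' Split text into sentence spans
#'
#' The default splitter is rule-based: sentences end at sentence-final
#' punctuation (`.`, `!`, `?`, runs included in the sentence) or at a
#' newline. Sentence spans tile the non-whitespace text, and each
#' sentence carries word-level token spans covering all its
#' non-whitespace characters. A different strategy (e.g. a model-based
#' splitter) can be injected wherever a `splitter` argument is accepted:
#' any function from text to a list of sentence spans with this shape
#' qualifies.
#'
#' @param text Document text.
#' @param split_minus Passed to [tokenize_spans()].
#' @return List of sentence spans: each `list(start, end, tokens)` with
#'   0-based half-open character offsets and a token data frame as
#'   returned by [tokenize_spans()] (token offsets are global, i.e. into
#'   `text`).
#' @export
split_sentences <- function(text, split_minus = FALSE) {
  if (!nzchar(text)) return(list())
  m <- gregexpr("[^.!?\n]*[.!?]+|[^.!?\n]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list())
  len <- attr(m, "match.length")
  out <- list()
  for (i in seq_along(m)) {
    seg <- substring(text, m[i], m[i] + len[i] - 1L)
    # trim whitespace off the raw segment so spans cover non-ws text only
    lead <- nchar(sub("^(\\s*).*$", "\\1", seg, perl = TRUE))
    core <- trimws(seg)
    if (!nzchar(core)) next
    start0 <- as.integer(m[i]) - 1L + lead          # 0-based
    end0 <- start0 + nchar(core)
    toks <- tokenize_spans(core, split_minus = split_minus)
    toks$start <- toks$start + start0
    toks$end <- toks$end + start0
    out[[length(out) + 1L]] <- list(start = start0, end = end0,
                                    tokens = toks)
  }
  out
}

# tokens that count as "words" for word-count scopes and length statistics
is_word_token <- function(tokens) {
  grepl("[\\p{L}\\p{N}]", tokens, perl = TRUE)
}
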