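# Continuous-bag-of-words embedding trainer: predict the center token
# from the average of its context vectors, full-softmax output layer,
# plain SGD. Small and deterministic; meant for modest domain corpora.

#' Train CBOW word embeddings
#'
#' The training objective predicts each center token from the average of
#' the input vectors of its context window, through a softmax over the
#' vocabulary. Optimized by stochastic gradient descent; fully
#' reproducible under `seed`.
#'
#' @param texts Non-empty character vector of training text.
#' @param dim Embedding dimension (>= 1).
#' @param context_window Tokens on each side of the center (default 5).
#' @param seed RNG seed.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param tokenizer Optional [train_bpe()] tokenizer; when given, texts
#'   are subword-tokenized (whitespace tokens dropped), otherwise
#'   whitespace word tokens are used.
#' @return An `embedding_table`: numeric matrix, one row per vocabulary
#'   token (rownames are the tokens), with attribute `loss_history`
#'   (mean cross-entropy per epoch).
#' @export
pretrain_cbow <- function(texts, dim, context_window = 5L, seed = 1L,
                          epochs = 5L, lr = 0.05, tokenizer = NULL) {
  texts <- texts[nzchar(texts)]
  if (!length(texts)) stop("pretrain_cbow: empty corpus")
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L)
    stop("pretrain_cbow: configuration error: dim must be >= 1")

  seqs <- lapply(texts, function(x) {
    toks <- if (is.null(tokenizer)) {
      t0 <- unlist(strsplit(x, "\\s+", perl = TRUE))
      t0[nzchar(t0)]
    } else {
      t0 <- bpe_encode(tokenizer, x)
      t0[!grepl("^\\s+$", t0)]
    }
    toks
  })
  vocab <- sort(unique(unlist(seqs)), method = "radix")
  if (!length(vocab)) stop("pretrain_cbow: corpus has no tokens")
  ids <- lapply(seqs, match, table = vocab)
  V <- length(vocab)

  set.seed(seed)
  Vin <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
  Vout <- matrix(0, V, dim)

  # precompute (center, context) examples
  centers <- integer(0); ctx <- list()
  for (s in ids) {
    n <- length(s)
    if (n < 2L) next
    for (c in seq_len(n)) {
      lo <- max(1L, c - context_window); hi <- min(n, c + context_window)
      cc <- s[setdiff(lo:hi, c)]
      if (!length(cc)) next
      centers <- c(centers, s[c]); ctx[[length(ctx) + 1L]] <- cc
    }
  }
  if (!length(centers)) stop("pretrain_cbow: no training contexts")

  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(centers))
    total <- 0
    for (j in ord) {
      cc <- ctx[[j]]
      h <- colMeans(Vin[cc, , drop = FALSE])          # dim
      scores <- as.numeric(Vout %*% h)                # V
      scores <- scores - max(scores)
      p <- exp(scores); p <- p / sum(p)
      y <- centers[j]
      total <- total - log(max(p[y], 1e-12))
      dscore <- p; dscore[y] <- dscore[y] - 1
      dh <- as.numeric(crossprod(Vout, dscore))       # dim
      Vout <- Vout - lr * tcrossprod(dscore, h)
      upd <- lr * dh / length(cc)
      for (w in cc) Vin[w, ] <- Vin[w, ] - upd
    }
    loss_history[ep] <- total / length(centers)
  }
  rownames(Vin) <- vocab
  structure(Vin, loss_history = loss_history, class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x), " tokens x ", ncol(x), " dims\n",
      sep = "")
  invisible(x)
}
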