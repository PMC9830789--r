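# Recurrent negation classifier: entity-placeholder abstraction, fixed
# asymmetric token windows, optional CBOW-initialized embeddings, a
# bidirectional LSTM encoder and a fully-connected head. Forward pass and
# backpropagation-through-time are written out with BLAS matrix products;
# no external deep-learning runtime is involved.

#' Window configuration for the recurrent classifier
#'
#' The classifier observes a fixed asymmetric window around the annotated
#' concept: by default 15 tokens to the left and 10 to the right, counted
#' in word tokens before subword encoding (so the window semantics do not
#' depend on the subword vocabulary size).
#'
#' @param left_tokens,right_tokens Non-negative window sizes
#'   (defaults 15 and 10).
#' @param placeholder_symbol Reserved token replacing the entity surface;
#'   must never collide with corpus vocabulary (the default cannot be
#'   produced by the word tokenizer).
#' @return A `window_config`.
#' @export
window_config <- function(left_tokens = 15L, right_tokens = 10L,
                          placeholder_symbol = "[TERM]") {
  left_tokens <- as.integer(left_tokens); right_tokens <- as.integer(right_tokens)
  if (is.na(left_tokens) || left_tokens < 0L ||
      is.na(right_tokens) || right_tokens < 0L)
    stop("window_config: window sizes must be non-negative")
  structure(list(left_tokens = left_tokens, right_tokens = right_tokens,
                 placeholder_symbol = placeholder_symbol),
            class = "window_config")
}

#' Replace an entity by a placeholder inside its token window
#'
#' Entity tokens are replaced by a single placeholder symbol; up to
#' `left_tokens` tokens before and `right_tokens` after are retained,
#' clipped at the document edges. Two examples differing only in entity
#' surface therefore produce identical model inputs ("no signs of
#' \[TERM\]" is learned once, not once per disease).
#'
#' @param tokens Character vector of word tokens.
#' @param entity_range Integer 1-based inclusive `c(from, to)` token
#'   range of the entity; must be non-empty and within `tokens`.
#' @param config A [window_config()].
#' @return Character vector of window tokens with attribute
#'   `placeholder_pos` (index of the placeholder).
#' @export
abstract_entity <- function(tokens, entity_range, config = window_config()) {
  n <- length(tokens)
  from <- entity_range[1]; to <- entity_range[length(entity_range)]
  if (is.na(from) || is.na(to) || from > to || from < 1L || to > n)
    stop("abstract_entity: entity range [", from, ", ", to,
         "] empty or outside 1..", n)
  left <- if (from > 1L) tokens[max(1L, from - config$left_tokens):(from - 1L)]
          else character(0)
  right <- if (to < n) tokens[(to + 1L):min(n, to + config$right_tokens)]
           else character(0)
  out <- c(left, config$placeholder_symbol, right)
  attr(out, "placeholder_pos") <- length(left) + 1L
  out
}

#' Build placeholder-abstracted training examples from a corpus
#'
#' Word-tokenizes each document, windows each gold-labeled entity with
#' [abstract_entity()] and (when a tokenizer is given) subword-encodes
#' the context tokens; the placeholder stays one atomic token.
#'
#' @param docs Corpus of `annotated_document`s with gold labels.
#' @param config A [window_config()].
#' @param tokenizer Optional `bpe_tokenizer`.
#' @return List of `training_example`s: `list(tokens, placeholder_index,
#'   label, doc_id, entity_index)`.
#' @export
build_training_examples <- function(docs, config = window_config(),
                                    tokenizer = NULL) {
  cache <- new.env(parent = emptyenv())
  encode1 <- function(w) {
    if (is.null(tokenizer)) return(w)
    hit <- cache[[w]]
    if (is.null(hit)) {
      hit <- bpe_encode(tokenizer, w)
      cache[[w]] <- hit
    }
    hit
  }
  out <- list()
  for (d in docs) {
    toks <- tokenize_spans(d$text)
    for (k in seq_along(d$entities)) {
      e <- d$entities[[k]]
      rng <- which(toks$start < e$end & toks$end > e$start)
      if (!length(rng)) next
      win <- abstract_entity(toks$token, c(min(rng), max(rng)), config)
      pos <- attr(win, "placeholder_pos")
      sub <- lapply(seq_along(win), function(i) {
        if (i == pos) config$placeholder_symbol else encode1(win[i])
      })
      lens <- lengths(sub)
      ppos <- sum(lens[seq_len(pos - 1L)]) + 1L
      out[[length(out) + 1L]] <- structure(
        list(tokens = unlist(sub), placeholder_index = ppos,
             label = e$gold_label, doc_id = d$doc_id, entity_index = k),
        class = "training_example")
    }
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

default_bilstm_hyperparams <- function() {
  list(embedding_dim = 300L, hidden_size = 128L, fc_hidden = 64L,
       epochs = 15L, lr = 2e-3, batch_size = 32L, clip_norm = 5,
       class_weighting = FALSE, threshold = 0.5)
}

lstm_init <- function(E, H) {
  r <- function(n, m) matrix(stats::runif(n * m, -1, 1) / sqrt(m), n, m)
  list(Wx = r(E, 4L * H), Wh = r(H, 4L * H), b = numeric(4L * H))
}

# One-direction LSTM forward over a padded batch. ids: B x T (0 = pad).
lstm_forward <- function(ids, emb, par, H, keep_cache = FALSE) {
  B <- nrow(ids); T <- ncol(ids); E <- ncol(emb)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    idt <- ids[, t]
    X <- matrix(0, B, E)
    nz <- idt > 0L
    if (any(nz)) X[nz, ] <- emb[idt[nz], , drop = FALSE]
    A <- X %*% par$Wx + h %*% par$Wh
    A <- sweep(A, 2L, par$b, "+")
    i <- sigmoid(A[, 1:H, drop = FALSE])
    f <- sigmoid(A[, H + (1:H), drop = FALSE])
    g <- tanh(A[, 2L * H + (1:H), drop = FALSE])
    o <- sigmoid(A[, 3L * H + (1:H), drop = FALSE])
    cn <- f * cc + i * g
    hn <- o * tanh(cn)
    m <- as.numeric(nz)
    h_new <- m * hn + (1 - m) * h
    c_new <- m * cn + (1 - m) * cc
    if (keep_cache)
      cache[[t]] <- list(X = X, h_prev = h, c_prev = cc, i = i, f = f,
                         g = g, o = o, cn = cn, m = m, idt = idt)
    h <- h_new; cc <- c_new
  }
  list(h = h, cache = cache)
}

# BPTT for one direction; returns parameter grads and embedding grad.
lstm_backward <- function(dh_final, cache, par, emb_dim, H, V) {
  T <- length(cache)
  B <- nrow(dh_final)
  dWx <- matrix(0, emb_dim, 4L * H); dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  demb <- matrix(0, V, emb_dim)
  dh <- dh_final; dc <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    cc <- cache[[t]]
    m <- cc$m
    dh_new <- dh * m
    tanc <- tanh(cc$cn)
    dcn <- dc * m + dh_new * cc$o * (1 - tanc^2)
    di <- dcn * cc$g
    df <- dcn * cc$c_prev
    dg <- dcn * cc$i
    do_ <- dh_new * tanc
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$X, dA)
    dWh <- dWh + crossprod(cc$h_prev, dA)
    db <- db + colSums(dA)
    dX <- dA %*% t(par$Wx)
    nz <- cc$idt > 0L
    if (any(nz)) {
      agg <- rowsum(dX[nz, , drop = FALSE], group = cc$idt[nz])
      rows <- as.integer(rownames(agg))
      demb[rows, ] <- demb[rows, , drop = FALSE] + agg
    }
    dh <- dA %*% t(par$Wh) + dh * (1 - m)
    dc <- dcn * cc$f + dc * (1 - m)
  }
  list(dWx = dWx, dWh = dWh, db = db, demb = demb)
}

adam_new <- function(shapes) {
  lapply(shapes, function(x) list(m = x * 0, v = x * 0))
}
adam_step <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the bidirectional recurrent negation classifier
#'
#' Trains a one-layer-per-direction bidirectional LSTM over the subword
#' ids of placeholder-abstracted windows; the concatenated final states
#' feed one hidden fully-connected layer and a sigmoid output, optimized
#' with Adam on (optionally class-weighted) cross-entropy. Training is
#' fully reproducible under `seed`.
#'
#' @param examples List of `training_example`s (see
#'   [build_training_examples()]) with at least one example per class.
#' @param embeddings Optional `embedding_table` from [pretrain_cbow()];
#'   known tokens are initialized from it (and it fixes
#'   `embedding_dim`), unknown ones randomly. Embeddings stay trainable.
#' @param hyperparams Named list overriding the defaults
#'   `embedding_dim = 300`, `hidden_size = 128`, `fc_hidden = 64`,
#'   `epochs = 15`, `lr = 2e-3`, `batch_size = 32`,
#'   `class_weighting = FALSE` (inverse-frequency weights for the ~14%
#'   negated class), `threshold = 0.5`.
#' @param seed RNG seed.
#' @param tokenizer Optional `bpe_tokenizer`, stored for end-to-end
#'   prediction on raw corpora.
#' @param config Optional [window_config()], stored likewise.
#' @return A `context_classifier` with attribute-free list fields
#'   including `loss_history` (mean training loss per epoch).
#' @export
train_classifier <- function(examples, embeddings = NULL,
                             hyperparams = list(), seed = 1L,
                             tokenizer = NULL, config = NULL) {
  hp <- utils::modifyList(default_bilstm_hyperparams(), hyperparams)
  labels <- vapply(examples, `[[`, character(1), "label")
  for (lab in negation_labels())
    if (!any(labels == lab))
      stop("train_classifier: validation error: no examples of class '",
           lab, "'")

  vocab <- sort(unique(unlist(lapply(examples, `[[`, "tokens"))),
                method = "radix")
  if (!is.null(embeddings))
    vocab <- sort(unique(c(vocab, rownames(embeddings))), method = "radix")
  vocab <- c(vocab, "<unk>")
  V <- length(vocab)
  E <- if (!is.null(embeddings)) ncol(embeddings) else hp$embedding_dim
  H <- hp$hidden_size; D1 <- hp$fc_hidden

  set.seed(seed)
  emb <- matrix(stats::runif(V * E, -0.5, 0.5) / E, V, E)
  if (!is.null(embeddings)) {
    hit <- match(rownames(embeddings), vocab)
    emb[hit, ] <- unclass(embeddings)[, , drop = FALSE]
  }
  fwd <- lstm_init(E, H); bwd <- lstm_init(E, H)
  r <- function(n, m) matrix(stats::runif(n * m, -1, 1) / sqrt(n), n, m)
  W1 <- r(2L * H, D1); b1 <- numeric(D1)
  W2 <- r(D1, 1L); b2 <- 0

  ids_list <- lapply(examples, function(ex) {
    id <- match(ex$tokens, vocab)
    id[is.na(id)] <- V
    id
  })
  y <- as.numeric(labels == "negated")
  w <- rep(1, length(y))
  if (isTRUE(hp$class_weighting)) {
    pos <- mean(y)
    w <- ifelse(y == 1, 0.5 / max(pos, 1e-6), 0.5 / max(1 - pos, 1e-6))
  }

  params <- list(emb = emb, fWx = fwd$Wx, fWh = fwd$Wh, fb = fwd$b,
                 bWx = bwd$Wx, bWh = bwd$Wh, bb = bwd$b,
                 W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  opt <- adam_new(params)
  step <- 0L
  loss_history <- numeric(hp$epochs)
  n <- length(examples)
  for (ep in seq_len(hp$epochs)) {
    ord <- sample.int(n)
    total <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / hp$batch_size))) {
      B <- length(bs)
      lens <- lengths(ids_list[bs])
      T <- max(lens)
      idsF <- matrix(0L, B, T); idsB <- matrix(0L, B, T)
      for (r2 in seq_len(B)) {
        s <- ids_list[[bs[r2]]]
        idsF[r2, seq_along(s)] <- s
        idsB[r2, seq_along(s)] <- rev(s)
      }
      yb <- y[bs]; wb <- w[bs]

      ff <- lstm_forward(idsF, params$emb,
                         list(Wx = params$fWx, Wh = params$fWh, b = params$fb),
                         H, keep_cache = TRUE)
      bb_ <- lstm_forward(idsB, params$emb,
                          list(Wx = params$bWx, Wh = params$bWh, b = params$bb),
                          H, keep_cache = TRUE)
      Z <- cbind(ff$h, bb_$h)
      U1 <- sweep(Z %*% params$W1, 2L, params$b1, "+")
      R <- pmax(U1, 0)
      logit <- as.numeric(R %*% params$W2) + params$b2
      p <- sigmoid(logit)
      pc <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      total <- total - sum(wb * (yb * log(pc) + (1 - yb) * log(1 - pc)))

      dlogit <- matrix(wb * (p - yb) / B, ncol = 1L)
      dW2 <- crossprod(R, dlogit); db2 <- sum(dlogit)
      dR <- dlogit %*% t(params$W2)
      dU1 <- dR * (U1 > 0)
      dW1 <- crossprod(Z, dU1); db1 <- colSums(dU1)
      dZ <- dU1 %*% t(params$W1)
      gF <- lstm_backward(dZ[, 1:H, drop = FALSE], ff$cache,
                          list(Wx = params$fWx, Wh = params$fWh), E, H, V)
      gB <- lstm_backward(dZ[, H + (1:H), drop = FALSE], bb_$cache,
                          list(Wx = params$bWx, Wh = params$bWh), E, H, V)
      grads <- list(emb = gF$demb + gB$demb,
                    fWx = gF$dWx, fWh = gF$dWh, fb = gF$db,
                    bWx = gB$dWx, bWh = gB$dWh, bb = gB$db,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
      # global-norm gradient clipping keeps BPTT stable
      if (is.finite(hp$clip_norm)) {
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gnorm > hp$clip_norm)
          grads <- lapply(grads, function(g) g * (hp$clip_norm / gnorm))
      }
      step <- step + 1L
      for (nm in names(params)) {
        upd <- adam_step(params[[nm]], grads[[nm]], opt[[nm]], hp$lr, step)
        params[[nm]] <- upd$param; opt[[nm]] <- upd$state
      }
    }
    loss_history[ep] <- total / n
  }
  structure(list(vocab = vocab, params = params, hyperparams = hp,
                 loss_history = loss_history, tokenizer = tokenizer,
                 window = config, threshold = hp$threshold),
            class = "context_classifier")
}

#' @export
print.context_classifier <- function(x, ...) {
  cat("<context_classifier> biLSTM, vocab ", length(x$vocab), ", hidden ",
      x$hyperparams$hidden_size, ", final loss ",
      signif(utils::tail(x$loss_history, 1), 4), "\n", sep = "")
  invisible(x)
}

classifier_probs <- function(object, examples) {
  V <- length(object$vocab); H <- object$hyperparams$hidden_size
  ids_list <- lapply(examples, function(ex) {
    id <- match(ex$tokens, object$vocab)
    id[is.na(id)] <- V                       # reserved unknown
    id
  })
  n <- length(ids_list)
  probs <- numeric(n)
  for (bs in split(seq_len(n), ceiling(seq_len(n) / 256L))) {
    B <- length(bs)
    T <- max(lengths(ids_list[bs]))
    idsF <- matrix(0L, B, T); idsB <- matrix(0L, B, T)
    for (r2 in seq_len(B)) {
      s <- ids_list[[bs[r2]]]
      idsF[r2, seq_along(s)] <- s
      idsB[r2, seq_along(s)] <- rev(s)
    }
    p <- object$params
    hF <- lstm_forward(idsF, p$emb, list(Wx = p$fWx, Wh = p$fWh, b = p$fb), H)$h
    hB <- lstm_forward(idsB, p$emb, list(Wx = p$bWx, Wh = p$bWh, b = p$bb), H)$h
    Z <- cbind(hF, hB)
    R <- pmax(sweep(Z %*% p$W1, 2L, p$b1, "+"), 0)
    probs[bs] <- sigmoid(as.numeric(R %*% p$W2) + p$b2)
  }
  probs
}

#' Predict negation for placeholder-abstracted examples
#'
#' @param object A `context_classifier`.
#' @param examples List of `training_example`s (labels, if present, are
#'   ignored). Out-of-vocabulary tokens map to the reserved unknown
#'   token; prediction never fails on them.
#' @param ... Unused.
#' @return Prediction data frame (`doc_id`, `entity_index`, `label`,
#'   `probability`, `method = "bilstm"`); `label == "negated"` iff
#'   `probability >= threshold` (default 0.5, the `>=` rule).
#' @export
predict.context_classifier <- function(object, examples, ...) {
  probs <- classifier_probs(object, examples)
  data.frame(
    doc_id = vapply(examples, function(e)
      if (is.null(e$doc_id)) NA_character_ else e$doc_id, character(1)),
    entity_index = vapply(examples, function(e)
      if (is.null(e$entity_index)) NA_integer_ else e$entity_index,
      integer(1)),
    label = ifelse(probs >= object$threshold, "negated", "not_negated"),
    probability = probs,
    method = "bilstm",
    stringsAsFactors = FALSE)
}

#' Train the recurrent classifier end-to-end on a corpus
#'
#' Convenience wrapper: trains the BPE tokenizer on the corpus text,
#' optionally pretrains CBOW embeddings, builds placeholder-abstracted
#' examples from the gold labels and trains the classifier.
#'
#' @param docs Gold-labeled corpus.
#' @param config A [window_config()].
#' @param vocab_size BPE vocabulary size.
#' @param use_cbow Pretrain CBOW embeddings on the corpus text.
#' @param cbow_dim,cbow_epochs CBOW settings (dim defaults to the
#'   classifier's embedding dim).
#' @param hyperparams,seed Passed to [train_classifier()].
#' @return A `context_classifier` carrying its tokenizer and window
#'   config, usable with [predict_corpus_bilstm()].
#' @export
train_bilstm <- function(docs, config = window_config(), vocab_size = 400L,
                         use_cbow = FALSE, cbow_dim = NULL,
                         cbow_epochs = 3L, hyperparams = list(), seed = 1L) {
  texts <- vapply(docs, `[[`, character(1), "text")
  tokenizer <- train_bpe(texts, vocab_size)
  hp <- utils::modifyList(default_bilstm_hyperparams(), hyperparams)
  embeddings <- NULL
  if (use_cbow) {
    if (is.null(cbow_dim)) cbow_dim <- hp$embedding_dim
    embeddings <- pretrain_cbow(texts, dim = cbow_dim, seed = seed,
                                epochs = cbow_epochs, tokenizer = tokenizer)
  }
  examples <- build_training_examples(docs, config, tokenizer)
  train_classifier(examples, embeddings = embeddings,
                   hyperparams = hyperparams, seed = seed,
                   tokenizer = tokenizer, config = config)
}

#' Predict negation for every entity of a corpus
#'
#' @param object A `context_classifier` trained with [train_bilstm()]
#'   (i.e. carrying tokenizer and window config).
#' @param docs Corpus.
#' @return Prediction data frame as [predict.context_classifier()].
#' @export
predict_corpus_bilstm <- function(object, docs) {
  if (is.null(object$window))
    stop("predict_corpus_bilstm: classifier lacks a stored window config")
  examples <- build_training_examples(docs, object$window, object$tokenizer)
  predict(object, examples)
}
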