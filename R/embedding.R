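#' Build the embedding corpus from a knowledge graph
#'
#' Each triple becomes one three-token sentence `(head, relation, tail)`.
#' The sentences, expanded so that every token is predicted once from the
#' other two, are the training corpus of the embedding model.
#'
#' @param kg An `adr_kg` object.
#' @return An `adr_corpus`: a tibble with columns `head`, `relation`, `tail`
#'   (tokens) carrying the graph vocabulary as an attribute; one row per
#'   triple.
#' @export
build_corpus <- function(kg) {
  stopifnot(inherits(kg, "adr_kg"))
  corpus <- kg$triples
  attr(corpus, "vocabulary") <- kg$vocabulary
  class(corpus) <- c("adr_corpus", class(corpus))
  corpus
}

corpus_vocabulary <- function(corpus) {
  v <- attr(corpus, "vocabulary")
  if (is.null(v)) stop("corpus has no vocabulary attribute", call. = FALSE)
  v
}

# Sentences as a T x 3 matrix of 1-based vocabulary indices.
corpus_index_matrix <- function(corpus) {
  vocab <- corpus_vocabulary(corpus)
  m <- cbind(
    match(corpus$head, vocab),
    match(corpus$relation, vocab),
    match(corpus$tail, vocab)
  )
  if (anyNA(m)) stop("corpus token missing from vocabulary", call. = FALSE)
  m
}

#' Expand sentences into context/target training samples
#'
#' Every 3-token sentence yields exactly three samples: each token once as
#' the prediction target with the remaining two as its (unordered) context.
#' Duplicate sentences yield duplicate samples.
#'
#' @param corpus An `adr_corpus` from [build_corpus()].
#' @return A tibble with columns `sentence` (row index into the corpus),
#'   `context1`, `context2`, `target` (tokens); `3 * nrow(corpus)` rows.
#' @export
expand_samples <- function(corpus) {
  stopifnot(inherits(corpus, "adr_corpus"))
  toks <- as.matrix(corpus[, c("head", "relation", "tail")])
  n <- nrow(toks)
  out <- tibble::tibble(
    sentence = rep(seq_len(n), each = 3),
    target_position = rep(1:3, times = n)
  )
  tm <- toks[out$sentence, , drop = FALSE]
  pick <- cbind(seq_len(nrow(out)), out$target_position)
  ctx <- t(vapply(seq_len(nrow(out)),
                  function(i) tm[i, -out$target_position[i]],
                  character(2)))
  out$context1 <- ctx[, 1]
  out$context2 <- ctx[, 2]
  out$target <- tm[pick]
  out
}

# Index-level sample expansion used by the trainer: rows 3i-2..3i are the
# three samples of sentence i (head, relation, tail each once as target).
expand_sample_indices <- function(sentences) {
  m <- nrow(sentences)
  out <- matrix(0L, nrow = 3L * m, ncol = 3)
  out[seq.int(1L, by = 3L, length.out = m), ] <-
    cbind(sentences[, 2], sentences[, 3], sentences[, 1])
  out[seq.int(2L, by = 3L, length.out = m), ] <-
    cbind(sentences[, 1], sentences[, 3], sentences[, 2])
  out[seq.int(3L, by = 3L, length.out = m), ] <-
    cbind(sentences[, 1], sentences[, 2], sentences[, 3])
  out
}

init_embedding <- function(vocab, size, seed) {
  n <- length(vocab)
  with_seed(seed, {
    W1 <- matrix(stats::runif(n * size, -0.5 / size, 0.5 / size),
                 nrow = n, ncol = size)
  })
  rownames(W1) <- vocab
  W2 <- matrix(0, nrow = size, ncol = n, dimnames = list(NULL, vocab))
  list(W1 = W1, W2 = W2)
}

new_embedding <- function(W1, W2, vocab, size, iters, mode, seed,
                          epoch_loss = numeric(0)) {
  structure(
    list(W1 = W1, W2 = W2, vocabulary = vocab, size = size, iters = iters,
         mode = mode, seed = seed, epoch_loss = epoch_loss),
    class = "adr_embedding"
  )
}

#' Train the knowledge-graph embedding model
#'
#' Trains the two weight matrices of the softmax context-prediction model
#' `f(x1, x2) = softmax((x1 + x2) W1 W2)` by stochastic gradient descent:
#' for every triple sentence, each token is predicted from the sum of the
#' other two tokens' input vectors. Entity vectors are the rows of `W1`.
#'
#' `mode = "full_softmax"` optimises the cross-entropy over the whole
#' vocabulary exactly as the model equations state; it is practical up to a
#' few tens of thousands of tokens. `mode = "negative_sampling"` replaces
#' the full softmax with one positive plus `negative` uniformly drawn
#' corrupted targets per sample, the usual large-vocabulary approximation.
#'
#' The learning rate decays linearly from `lr_initial` to `lr_final` across
#' all updates. Sentences are reshuffled every epoch. Given the same corpus,
#' parameters and seed the result is bit-for-bit reproducible;
#' `iters = 0` returns the seeded random initialisation unchanged
#' (`W1 ~ U(-0.5/size, 0.5/size)`, `W2 = 0`).
#'
#' @param corpus An `adr_corpus` from [build_corpus()].
#' @param size Embedding dimension (default 800, the dimension at which
#'   held-out prediction performance saturates on the full-scale graph).
#' @param iters Number of passes over the corpus (default 2500, the
#'   saturating iteration count on the full-scale graph; use far fewer for
#'   small graphs).
#' @param mode `"full_softmax"` (default, faithful to the model equations)
#'   or `"negative_sampling"`.
#' @param lr_initial,lr_final Learning-rate schedule endpoints.
#' @param negative Number of negative draws per sample in
#'   `negative_sampling` mode.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   negative draws.
#' @return An `adr_embedding`: `W1` (n x size, rows named by token), `W2`
#'   (size x n), the vocabulary, training settings and the per-epoch mean
#'   training loss.
#' @examples
#' g <- synth_kg(n_drugs = 20, n_side_effects = 20, n_targets = 10,
#'               n_indications = 10, seed = 1)
#' emb <- train_embedding(build_corpus(g$kg), size = 8, iters = 20, seed = 1)
#' glance(emb)
#' @export
train_embedding <- function(corpus, size = 800, iters = 2500,
                            mode = c("full_softmax", "negative_sampling"),
                            lr_initial = 0.025, lr_final = 1e-4,
                            negative = 5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "adr_corpus"), size >= 1, iters >= 0)
  if (nrow(corpus) == 0) stop("empty corpus", call. = FALSE)
  vocab <- corpus_vocabulary(corpus)
  sentences <- corpus_index_matrix(corpus)
  samples <- expand_sample_indices(sentences) - 1L
  storage.mode(samples) <- "integer"

  with_seed(seed, {
    n <- length(vocab)
    W1 <- matrix(stats::runif(n * size, -0.5 / size, 0.5 / size),
                 nrow = n, ncol = size)
    if (iters == 0) {
      W2 <- matrix(0, nrow = size, ncol = n)
      fit <- list(W1t = t(W1), W2 = W2, epoch_loss = numeric(0))
    } else {
      fit <- sgd_train_cpp(t(W1), matrix(0, nrow = size, ncol = n), samples,
                           as.integer(iters), lr_initial, lr_final,
                           mode == "negative_sampling", as.integer(negative))
    }
  })

  W1 <- t(fit$W1t)
  rownames(W1) <- vocab
  colnames(fit$W2) <- vocab
  new_embedding(W1, fit$W2, vocab, size, iters, mode, seed,
                epoch_loss = as.numeric(fit$epoch_loss))
}

resolve_token <- function(model, token) {
  if (is.numeric(token)) {
    idx <- as.integer(token)
    if (any(idx < 1 | idx > length(model$vocabulary))) {
      stop("token index out of range", call. = FALSE)
    }
  } else {
    idx <- match(token, model$vocabulary)
    if (anyNA(idx)) {
      stop("unknown token(s): ", paste(token[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  }
  idx
}

#' Probability distribution over the vocabulary for a context pair
#'
#' Evaluates the forward pass `softmax((x1 + x2) W1 W2)`: the two context
#' tokens' input vectors are summed, projected through the output matrix and
#' normalised by softmax. Entries lie in (0, 1) and sum to one.
#'
#' @param model An `adr_embedding`.
#' @param context Two tokens (ids or vocabulary indices).
#' @return A named numeric vector of length n (the vocabulary size).
#' @export
forward_probabilities <- function(model, context) {
  stopifnot(inherits(model, "adr_embedding"), length(context) == 2)
  idx <- resolve_token(model, context)
  h <- model$W1[idx[1], ] + model$W1[idx[2], ]
  u <- drop(h %*% model$W2)
  u <- u - max(u)
  p <- exp(u)
  p <- p / sum(p)
  stats::setNames(p, model$vocabulary)
}

#' Cross-entropy loss of one context/target sample
#'
#' Returns `-log p(target | context)` with the probability taken from
#' [forward_probabilities()]; strictly positive unless the model puts all
#' mass on the target.
#'
#' @param model An `adr_embedding`.
#' @param context Two tokens (ids or indices).
#' @param target The token to be predicted.
#' @return Non-negative scalar loss.
#' @export
sample_loss <- function(model, context, target) {
  p <- forward_probabilities(model, context)
  idx <- resolve_token(model, target)
  -log(p[[idx]])
}

#' Mean training loss of a model over a corpus
#'
#' Averages the per-sample cross-entropy over all `3 * nrow(corpus)`
#' context/target samples of the corpus (the training objective divided by
#' the sample count), computed exactly with the full softmax.
#'
#' @param model An `adr_embedding`.
#' @param corpus An `adr_corpus` over the same vocabulary.
#' @return Scalar mean loss.
#' @export
corpus_loss <- function(model, corpus) {
  stopifnot(inherits(model, "adr_embedding"), inherits(corpus, "adr_corpus"))
  sentences <- corpus_index_matrix(corpus)
  samples <- expand_sample_indices(sentences)
  H <- model$W1[samples[, 1], , drop = FALSE] +
    model$W1[samples[, 2], , drop = FALSE]
  U <- H %*% model$W2
  umax <- apply(U, 1, max)
  lse <- umax + log(rowSums(exp(U - umax)))
  tgt <- U[cbind(seq_len(nrow(U)), samples[, 3])]
  mean(lse - tgt)
}

# Analytic gradients of the single-sample cross-entropy w.r.t. W1 and W2;
# dW1 is non-zero only in the two context rows. Used to validate the
# compiled trainer against finite differences.
embedding_gradients <- function(model, context, target) {
  idx <- resolve_token(model, context)
  t_idx <- resolve_token(model, target)
  h <- model$W1[idx[1], ] + model$W1[idx[2], ]
  p <- unname(forward_probabilities(model, context))
  e <- p
  e[t_idx] <- e[t_idx] - 1
  dW2 <- outer(h, e)
  dh <- drop(model$W2 %*% e)
  dW1 <- matrix(0, nrow = nrow(model$W1), ncol = ncol(model$W1))
  dW1[idx[1], ] <- dW1[idx[1], ] + dh
  dW1[idx[2], ] <- dW1[idx[2], ] + dh
  list(dW1 = dW1, dW2 = dW2)
}

#' Look up an entity vector
#'
#' Entity (and relation) vectors are the rows of the input matrix `W1`.
#'
#' @param model An `adr_embedding`.
#' @param token Token id (string) or vocabulary index.
#' @return Numeric vector of length `size`.
#' @export
entity_vector <- function(model, token) {
  stopifnot(inherits(model, "adr_embedding"), length(token) == 1)
  model$W1[resolve_token(model, token), ]
}

#' Write entity vectors in word2vec text format
#'
#' Header line `n size`, then one `token v1 ... vsize` line per token.
#'
#' @param model An `adr_embedding`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(model, path) {
  stopifnot(inherits(model, "adr_embedding"))
  n <- length(model$vocabulary)
  if (n == 0) stop("refusing to write an empty-vocabulary model", call. = FALSE)
  rows <- vapply(seq_len(n), function(i) {
    paste(model$vocabulary[i],
          paste(formatC(model$W1[i, ], format = "g", digits = 9),
                collapse = " "))
  }, character(1))
  readr::write_lines(c(paste(n, model$size), rows), path)
  invisible(path)
}

#' Read word2vec text-format vectors
#'
#' @param path Path to a file written by [write_vectors()] (or any
#'   word2vec-text file).
#' @return A numeric matrix with one row per token, rownames set to tokens.
#' @export
read_vectors <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) < 1) stop("empty vector file", call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2) stop("malformed word2vec header", call. = FALSE)
  n <- as.integer(header[1]); size <- as.integer(header[2])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) != n) {
    stop(sprintf("header declares %d vectors but file has %d rows",
                 n, length(body)), call. = FALSE)
  }
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != size + 1)) {
    stop("vector row arity does not match declared size", call. = FALSE)
  }
  W <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(W) <- vapply(parts, `[[`, character(1), 1)
  W
}

#' @export
print.adr_embedding <- function(x, ...) {
  cat("<adr_embedding>", length(x$vocabulary), "tokens, size", x$size,
      ",", x$iters, "epochs,", x$mode, "\n")
  if (length(x$epoch_loss) > 0) {
    cat(sprintf("  mean training loss: %.4f -> %.4f\n",
                x$epoch_loss[1], x$epoch_loss[length(x$epoch_loss)]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an embedding into a token table
#'
#' @param x An `adr_embedding`.
#' @param ... Unused.
#' @return A tibble with `token` and one `d1 ... d<size>` column per
#'   embedding dimension.
#' @export
tidy.adr_embedding <- function(x, ...) {
  W <- x$W1
  colnames(W) <- paste0("d", seq_len(ncol(W)))
  dplyr::bind_cols(tibble::tibble(token = x$vocabulary),
                   tibble::as_tibble(W))
}

#' One-row training summary of an embedding
#'
#' @param x An `adr_embedding`.
#' @param ... Unused.
#' @return A tibble with vocabulary size, dimension, epochs, mode and the
#'   first/last epoch mean losses (NA when `iters = 0`).
#' @export
glance.adr_embedding <- function(x, ...) {
  tibble::tibble(
    n_tokens = length(x$vocabulary),
    size = x$size,
    iters = x$iters,
    mode = x$mode,
    initial_loss = if (length(x$epoch_loss)) x$epoch_loss[1] else NA_real_,
    final_loss = if (length(x$epoch_loss))
      x$epoch_loss[length(x$epoch_loss)] else NA_real_
  )
}

#' Plot the training-loss trajectory of an embedding
#'
#' @param object An `adr_embedding` trained for at least one epoch.
#' @param ... Unused.
#' @return A ggplot of mean training loss per epoch.
#' @export
autoplot.adr_embedding <- function(object, ...) {
  stopifnot(length(object$epoch_loss) > 0)
  df <- tibble::tibble(epoch = seq_along(object$epoch_loss),
                       loss = object$epoch_loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean training loss")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
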