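test_that("corpus sentences mirror triples and expand to three samples each", {
  kg <- toy_kg_3()
  corpus <- build_corpus(kg)
  expect_equal(nrow(corpus), 3)
  expect_equal(corpus$head[1], "D1")
  expect_equal(corpus$relation[1], "has_side_effect")
  expect_equal(corpus$tail[1], "S1")

  samples <- expand_samples(corpus)
  expect_equal(nrow(samples), 9)
  # within each sentence every token is the target exactly once and the
  # three targets are disjoint
  per <- dplyr::filter(samples, sentence == 1)
  expect_setequal(per$target, c("D1", "has_side_effect", "S1"))
  expect_equal(anyDuplicated(per$target), 0)
  # context is always the complementary pair
  expect_setequal(unlist(per[per$target == "D1", c("context1", "context2")]),
                  c("has_side_effect", "S1"))
})

test_that("duplicate sentences keep duplicate samples", {
  kg <- kg_build(tibble::tibble(head = c("D1", "D2"),
                                relation = "has_side_effect",
                                tail = c("S1", "S1")))
  corpus <- build_corpus(kg)
  dup <- corpus[c(1, 1), ]
  attr(dup, "vocabulary") <- attr(corpus, "vocabulary")
  class(dup) <- class(corpus)
  expect_equal(nrow(expand_samples(dup)), 6)
})

test_that("forward probabilities are a valid softmax with the stated symmetries", {
  W1 <- matrix(0, nrow = 5, ncol = 3,
               dimnames = list(paste0("t", 1:5), NULL))
  model <- mk_embedding(W1)
  p <- forward_probabilities(model, c("t1", "t2"))
  expect_equal(unname(p), rep(0.2, 5))

  # identical output columns j,k force p_j = p_k for any context
  set.seed(4)
  W1 <- matrix(rnorm(10), nrow = 5, ncol = 2,
               dimnames = list(paste0("t", 1:5), NULL))
  W2 <- matrix(rnorm(10), nrow = 2, ncol = 5,
               dimnames = list(NULL, paste0("t", 1:5)))
  W2[, 4] <- W2[, 2]
  model <- mk_embedding(W1, W2)
  p <- forward_probabilities(model, c("t3", "t5"))
  expect_equal(p[["t2"]], p[["t4"]])
  expect_equal(sum(p), 1, tolerance = 1e-12)

  expect_error(forward_probabilities(model, c(1, 9)), "out of range")
})

test_that("forward pass and sample loss match the brute-force oracle", {
  model <- toy_model_4()
  for (ctx in list(c(1, 2), c(2, 3), c(1, 4))) {
    expected <- oracle_forward(model$W1, model$W2, ctx[1], ctx[2])
    got <- unname(forward_probabilities(model, ctx))
    expect_equal(got, expected, tolerance = 1e-10)
    expect_equal(sample_loss(model, ctx, 3), -log(expected[3]),
                 tolerance = 1e-10)
  }
})

test_that("uniform models give log-vocabulary-size loss", {
  W1 <- matrix(0, nrow = 5, ncol = 2, dimnames = list(paste0("t", 1:5), NULL))
  expect_equal(sample_loss(mk_embedding(W1), c("t1", "t2"), "t3"), log(5))
  W1 <- matrix(0, nrow = 2, ncol = 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(sample_loss(mk_embedding(W1), c("a", "b"), "a"), log(2))
})

test_that("analytic gradients match central finite differences", {
  model <- toy_model_4()
  ctx <- c(1, 3); tgt <- 2
  grads <- adrkg:::embedding_gradients(model, ctx, tgt)

  loss_with_W1 <- function(M) {
    m <- model; m$W1 <- M; rownames(m$W1) <- rownames(model$W1)
    sample_loss(m, ctx, tgt)
  }
  loss_with_W2 <- function(M) {
    m <- model; m$W2 <- M
    sample_loss(m, ctx, tgt)
  }
  fd1 <- fd_gradient(loss_with_W1, model$W1)
  fd2 <- fd_gradient(loss_with_W2, model$W2)
  scale1 <- pmax(abs(fd1), 1e-3)
  scale2 <- pmax(abs(fd2), 1e-3)
  expect_lt(max(abs(grads$dW1 - fd1) / scale1), 1e-5)
  expect_lt(max(abs(grads$dW2 - fd2) / scale2), 1e-5)
})

test_that("zero iterations returns the seeded initialisation unchanged", {
  corpus <- build_corpus(toy_kg_3())
  m <- train_embedding(corpus, size = 4, iters = 0, seed = 99)
  n <- length(m$vocabulary)
  init <- adrkg:::with_seed(99, matrix(stats::runif(n * 4, -0.5 / 4, 0.5 / 4),
                                       nrow = n, ncol = 4))
  expect_equal(unname(m$W1), init)
  expect_true(all(m$W2 == 0))
  expect_length(m$epoch_loss, 0)
})

test_that("training overfits a single repeated sentence", {
  kg <- kg_build(tibble::tibble(head = "D1", relation = "has_side_effect",
                                tail = "S1"))
  corpus <- build_corpus(kg)
  rep_corpus <- corpus[rep(1, 8), ]
  attr(rep_corpus, "vocabulary") <- attr(corpus, "vocabulary")
  class(rep_corpus) <- class(corpus)
  model <- train_embedding(rep_corpus, size = 2, iters = 400,
                           lr_initial = 0.1, lr_final = 0.01, seed = 2)
  for (s in list(list(ctx = c("has_side_effect", "S1"), tgt = "D1"),
                 list(ctx = c("D1", "S1"), tgt = "has_side_effect"),
                 list(ctx = c("D1", "has_side_effect"), tgt = "S1"))) {
    p <- forward_probabilities(model, s$ctx)
    expect_gt(p[[s$tgt]], 0.9)
  }
})

test_that("training reduces the mean corpus loss on a small toy graph", {
  corpus <- build_corpus(toy_kg_3())
  before <- corpus_loss(train_embedding(corpus, size = 2, iters = 0, seed = 5),
                        corpus)
  after <- corpus_loss(train_embedding(corpus, size = 2, iters = 200, seed = 5),
                       corpus)
  expect_lt(after, before)
})

test_that("epoch losses are non-increasing under a small constant learning rate", {
  corpus <- build_corpus(toy_kg_3())
  m <- train_embedding(corpus, size = 2, iters = 150,
                       lr_initial = 0.01, lr_final = 0.01, seed = 3)
  expect_true(all(diff(m$epoch_loss) <= 1e-6))
})

test_that("training is bit-for-bit reproducible and order-robust", {
  g <- small_signal_kg(seed = 2)
  corpus <- build_corpus(g$kg)
  a <- train_embedding(corpus, size = 8, iters = 5, seed = 7)
  b <- train_embedding(corpus, size = 8, iters = 5, seed = 7)
  expect_identical(a$W1, b$W1)
  expect_identical(a$W2, b$W2)

  # permuting the sentence order changes the stream pairing but the model
  # quality, measured by mean corpus loss, stays within stochastic range
  perm <- withr::with_seed(1, sample(nrow(corpus)))
  corpus_p <- corpus[perm, ]
  attr(corpus_p, "vocabulary") <- attr(corpus, "vocabulary")
  class(corpus_p) <- class(corpus)
  c_model <- train_embedding(corpus_p, size = 8, iters = 5, seed = 7)
  la <- corpus_loss(a, corpus)
  lc <- corpus_loss(c_model, corpus)
  expect_lt(abs(la - lc) / la, 0.25)

  # both modes obey the same determinism contract
  d1 <- train_embedding(corpus, size = 8, iters = 3,
                        mode = "negative_sampling", seed = 7)
  d2 <- train_embedding(corpus, size = 8, iters = 3,
                        mode = "negative_sampling", seed = 7)
  expect_identical(d1$W1, d2$W1)
})

test_that("negative-sampling training also reduces full-softmax corpus loss", {
  g <- small_signal_kg(seed = 3)
  corpus <- build_corpus(g$kg)
  init <- train_embedding(corpus, size = 8, iters = 0, seed = 11)
  trained <- train_embedding(corpus, size = 8, iters = 30,
                             mode = "negative_sampling", seed = 11)
  expect_lt(corpus_loss(trained, corpus), corpus_loss(init, corpus))
})

test_that("entity vectors are rows of W1 with the configured size", {
  corpus <- build_corpus(toy_kg_3())
  m <- train_embedding(corpus, size = 6, iters = 0, seed = 1)
  v <- entity_vector(m, "D1")
  expect_length(v, 6)
  expect_equal(v, m$W1["D1", ])
  expect_equal(entity_vector(m, 4), m$W1[4, ])
  expect_error(entity_vector(m, "nope"), "unknown token")

  m2 <- train_embedding(corpus, size = 6, iters = 50, seed = 1)
  expect_false(isTRUE(all.equal(entity_vector(m2, "D1"),
                                entity_vector(m2, "D2"))))
})

test_that("word2vec text round-trip preserves vectors to 1e-6", {
  corpus <- build_corpus(toy_kg_3())
  m <- train_embedding(corpus, size = 2, iters = 20, seed = 8)
  path <- withr::local_tempfile(fileext = ".txt")
  write_vectors(m, path)
  lines <- readLines(path)
  expect_length(lines, length(m$vocabulary) + 1)
  expect_equal(lines[1], paste(length(m$vocabulary), 2))
  W <- read_vectors(path)
  expect_equal(rownames(W), m$vocabulary)
  expect_lt(max(abs(W - m$W1)), 1e-6)

  # header/arity mismatches are format errors
  writeLines(c("3 2", "a 1 2", "b 3 4"), path)
  expect_error(read_vectors(path), "header declares")
  writeLines(c("1 2", "a 1 2 3"), path)
  expect_error(read_vectors(path), "arity")

  empty <- mk_embedding(matrix(numeric(), nrow = 0, ncol = 2,
                               dimnames = list(character(), NULL)))
  expect_error(write_vectors(empty, path), "empty-vocabulary")
})

test_that("tidy and glance expose the token table and training summary", {
  corpus <- build_corpus(toy_kg_3())
  m <- train_embedding(corpus, size = 3, iters = 10, seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), length(m$vocabulary))
  expect_equal(names(td), c("token", "d1", "d2", "d3"))
  gl <- glance(m)
  expect_equal(gl$size, 3)
  expect_equal(gl$iters, 10)
  expect_lt(gl$final_loss, gl$initial_loss)
})
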