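test_that("feature vectors are attribute-minus-drug differences", {
  expect_equal(feature_vector(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(feature_vector(c(0.5, 1), c(1, 2)), c(0.5, 1))
  a <- c(0.3, -0.2, 1); b <- c(1, 0, -1)
  expect_equal(feature_vector(a, b), -feature_vector(b, a))
  expect_error(feature_vector(1:2, 1:3), "length")
})

test_that("predicted probability is the standard logistic link", {
  m0 <- mk_classifier(c(0, 0), 0)
  expect_equal(predict_probability(m0, c(3, -7)), 0.5)

  m <- mk_classifier(c(1, -1), 0.5)
  expect_equal(predict_probability(m, c(2, 1)), 1 / (1 + exp(-1.5)),
               tolerance = 1e-12)

  m1 <- mk_classifier(c(1, 0), 0)
  expect_lt(predict_probability(m1, c(1, 0)), predict_probability(m1, c(2, 0)))
  expect_equal(predict_probability(m1, c(1, 0)), 1 / (1 + exp(-1)))

  expect_error(predict_probability(m1, c(NA, 1)), "non-finite")
  expect_error(predict_probability(m1, 1), "length mismatch")

  # link symmetry: negating the parameters reflects the probability
  mneg <- mk_classifier(-m$w, -m$b)
  x <- c(0.7, -2)
  expect_equal(predict_probability(m, x) + predict_probability(mneg, x), 1)
})

# Embedding in which drug D<i> and attribute A<i> sit at hand-chosen points,
# so pair features are fully controlled.
line_embedding <- function(drug_pos, attr_pos) {
  stopifnot(length(drug_pos) == length(attr_pos))
  k <- length(drug_pos)
  W1 <- rbind(cbind(drug_pos, 0), cbind(attr_pos, 0))
  rownames(W1) <- c(paste0("D", seq_len(k)), paste0("A", seq_len(k)))
  mk_embedding(W1)
}

test_that("fit separates a 1-D toy and matches the convex oracle", {
  # positives at feature +1 (attr 1, drug 0), negatives at -1
  emb <- line_embedding(drug_pos = c(0, 1), attr_pos = c(1, 0))
  train <- dplyr::bind_rows(
    tibble::tibble(drug = rep("D1", 20), attribute = "A1", label = 1L),
    tibble::tibble(drug = rep("D2", 20), attribute = "A2", label = 0L)
  )
  fit <- fit_adr_classifier(train, emb, C = 1, seed = 1)
  expect_gt(fit$w[1], 0)
  preds <- score_pairs(fit, emb, train)
  expect_equal(mean((preds$probability >= 0.5) == (train$label == 1)), 1)

  X <- matrix(c(rep(1, 20), rep(-1, 20)), ncol = 1)
  y <- c(rep(1, 20), rep(0, 20))
  oracle <- oracle_logreg_fit(X, y, C = 1)
  expect_lt(abs(fit$objective - oracle$objective), 1e-4)
})

test_that("balanced contradictory labels on one feature give probability one half", {
  emb <- line_embedding(drug_pos = 0, attr_pos = 1)
  train <- dplyr::bind_rows(
    tibble::tibble(drug = rep("D1", 15), attribute = "A1", label = 1L),
    tibble::tibble(drug = rep("D1", 15), attribute = "A1", label = 0L)
  )
  fit <- fit_adr_classifier(train, emb, seed = 1)
  p <- predict_probability(fit, feature_vector(entity_vector(emb, "D1"),
                                               entity_vector(emb, "A1")))
  expect_equal(p, 0.5, tolerance = 1e-3)
})

test_that("2-D fits agree with independent convex optimisers within 1e-4", {
  set.seed(31)
  n <- 40
  X <- rbind(matrix(rnorm(n, mean = 1, sd = 0.4), ncol = 2),
             matrix(rnorm(n, mean = -1, sd = 0.4), ncol = 2))
  y <- rep(c(1, 0), each = n / 2)
  W1 <- rbind(matrix(0, nrow = n, ncol = 2), X)
  rownames(W1) <- c(paste0("D", seq_len(n)), paste0("A", seq_len(n)))
  emb <- mk_embedding(W1)
  train <- tibble::tibble(drug = paste0("D", seq_len(n)),
                          attribute = paste0("A", seq_len(n)),
                          label = as.integer(y))

  fit <- fit_adr_classifier(train, emb, C = 1, seed = 1)
  oracle <- oracle_logreg_fit(X, y, C = 1)
  expect_lt(abs(fit$objective - oracle$objective), 1e-4)
  expect_equal(oracle_logreg_objective(fit$w, fit$b, X, y, C = 1),
               fit$objective, tolerance = 1e-10)

  skip_if_not_installed("glmnet")
  # second independent solver: penalised coordinate descent; glmnet scales
  # the loss by 1/m and the ridge penalty by lambda, so lambda = 1/(C m)
  gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         lambda = 1 / nrow(X), standardize = FALSE,
                         thresh = 1e-14)
  gw <- as.numeric(gfit$beta)
  gb <- as.numeric(gfit$a0)
  expect_lt(abs(oracle_logreg_objective(gw, gb, X, y, C = 1) - fit$objective),
            1e-3)
})

test_that("flipping labels negates the fitted parameters", {
  set.seed(52)
  n <- 30
  X <- matrix(rnorm(2 * n), ncol = 2)
  y <- as.integer(X[, 1] + 0.5 * rnorm(n) > 0)
  W1 <- rbind(matrix(0, nrow = n, ncol = 2), X)
  rownames(W1) <- c(paste0("D", seq_len(n)), paste0("A", seq_len(n)))
  emb <- mk_embedding(W1)
  pairs <- tibble::tibble(drug = paste0("D", seq_len(n)),
                          attribute = paste0("A", seq_len(n)))
  f1 <- fit_adr_classifier(dplyr::mutate(pairs, label = y), emb, seed = 1)
  f2 <- fit_adr_classifier(dplyr::mutate(pairs, label = 1L - y), emb, seed = 1)
  expect_equal(f1$w, -f2$w, tolerance = 1e-4)
  expect_equal(f1$b, -f2$b, tolerance = 1e-4)
})

test_that("duplicate-row weighting equals explicit replication", {
  emb <- line_embedding(drug_pos = c(0, 0.5, 1), attr_pos = c(1, 0.2, 0))
  base <- tibble::tibble(
    drug = c("D1", "D2", "D3"), attribute = c("A1", "A2", "A3"),
    label = c(1L, 0L, 0L)
  )
  replicated <- dplyr::bind_rows(base[1, ], base[rep(2:3, each = 10), ])
  f_rows <- fit_adr_classifier(replicated, emb, seed = 1)
  f_wts <- fit_adr_classifier(replicated, emb, seed = 1,
                              collapse_duplicates = TRUE)
  expect_equal(f_rows$objective, f_wts$objective, tolerance = 1e-6)
  expect_equal(f_rows$w, f_wts$w, tolerance = 1e-3)
})

test_that("fit rejects degenerate inputs with clear errors", {
  emb <- line_embedding(drug_pos = 0, attr_pos = 1)
  one_class <- tibble::tibble(drug = "D1", attribute = "A1", label = 1L)
  expect_error(fit_adr_classifier(one_class, emb), "single class")
  missing_tok <- tibble::tibble(drug = c("D1", "DX"), attribute = c("A1", "A1"),
                                label = c(1L, 0L))
  expect_error(fit_adr_classifier(missing_tok, emb), "DX")
})

test_that("score_pairs equals elementwise single-pair prediction", {
  emb <- line_embedding(drug_pos = c(0, 0.5, -1), attr_pos = c(1, -0.5, 2))
  model <- mk_classifier(c(0.8, 0), -0.1)
  pairs <- tibble::tibble(drug = c("D1", "D2", "D3"),
                          attribute = c("A2", "A3", "A1"))
  scored <- score_pairs(model, emb, pairs)
  expect_equal(nrow(scored), 3)
  looped <- vapply(seq_len(3), function(i) {
    predict_probability(model, feature_vector(
      entity_vector(emb, pairs$drug[i]),
      entity_vector(emb, pairs$attribute[i])
    ))
  }, numeric(1))
  expect_equal(scored$probability, looped)

  empty <- score_pairs(model, emb, pairs[0, ])
  expect_equal(nrow(empty), 0)

  zero <- mk_classifier(c(0, 0), 0)
  expect_equal(score_pairs(zero, emb, pairs[1, ])$probability, 0.5)
})

test_that("drug ranking is descending with lexicographic tie-break", {
  emb <- line_embedding(drug_pos = c(0, 1, 1), attr_pos = c(2, 2, 2))
  model <- mk_classifier(c(1, 0), 0)
  ranked <- rank_drugs_for_adr(model, emb, "A1", drugs = c("D3", "D1", "D2"))
  # D1 has feature 2 (p high); D2 and D3 tie at feature 1
  expect_equal(ranked$drug, c("D1", "D2", "D3"))
  expect_true(all(diff(ranked$probability) <= 0))
  expect_equal(nrow(rank_drugs_for_adr(model, emb, "A1",
                                       drugs = c("D1", "D2"), top_n = 10)), 2)
  expect_equal(nrow(rank_drugs_for_adr(model, emb, "A1",
                                       drugs = c("D1", "D2", "D3"),
                                       top_n = 2)), 2)
  expect_error(rank_drugs_for_adr(model, emb, "nope", drugs = "D1"),
               "unknown ADR")
})

test_that("group means average probabilities per mapped group", {
  preds <- tibble::tibble(drug = c("d1", "d2", "d3"),
                          adr = "x",
                          probability = c(0.4, 0.6, 0.2))
  out <- group_mean_probability(preds, c(d1 = "A", d2 = "A", d3 = "B"))
  expect_equal(out$mean_probability[out$group == "A"], 0.5)
  expect_equal(out$mean_probability[out$group == "B"], 0.2)
  expect_equal(out$n[out$group == "A"], 2)

  two <- group_mean_probability(
    tibble::tibble(drug = c("a", "b", "c"), adr = "x",
                   probability = c(0.2, 0.8, 0.6)),
    tibble::tibble(drug = c("a", "b", "c"), group = c("g1", "g2", "g2"))
  )
  expect_equal(two$mean_probability, c(0.2, 0.7))

  expect_error(group_mean_probability(preds, c(d1 = "A")), "missing from grouping")
})

test_that("classifier text artifact and prediction CSV round-trip", {
  emb <- line_embedding(drug_pos = c(0, 1), attr_pos = c(1, 0))
  train <- dplyr::bind_rows(
    tibble::tibble(drug = rep("D1", 5), attribute = "A1", label = 1L),
    tibble::tibble(drug = rep("D2", 5), attribute = "A2", label = 0L)
  )
  fit <- fit_adr_classifier(train, emb, seed = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_classifier(fit, path)
  back <- read_classifier(path)
  expect_equal(back$w, fit$w, tolerance = 1e-12)
  expect_equal(back$b, fit$b, tolerance = 1e-12)
  expect_equal(back$size, fit$size)

  preds <- score_pairs(fit, emb, train[c(1, 6), ])
  csv <- withr::local_tempfile(fileext = ".csv")
  predictions_write(preds, csv)
  got <- readr::read_csv(csv, col_types = "ccd", progress = FALSE)
  expect_equal(names(got), c("drug_id", "adr_id", "probability"))
  expect_equal(got$probability, round(preds$probability, 6), tolerance = 1e-9)

  td <- tidy(fit)
  expect_equal(td$term[1], "(bias)")
  expect_equal(nrow(td), fit$size + 1)
  expect_true(glance(fit)$converged)
})
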