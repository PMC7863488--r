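# Independent oracles and small fixture builders. Everything here is
# written from the definitions directly (elementwise loops, exhaustive
# enumeration, generic optimisers) and never calls the package code paths
# it is used to check.

# Brute-force forward pass: softmax((x_c1 + x_c2) W1 W2) computed
# elementwise from one-hot vectors.
oracle_forward <- function(W1, W2, c1, c2) {
  n <- nrow(W1)
  x <- numeric(n)
  x[c1] <- x[c1] + 1
  x[c2] <- x[c2] + 1
  hidden <- numeric(ncol(W1))
  for (d in seq_len(ncol(W1))) {
    hidden[d] <- sum(x * W1[, d])
  }
  u <- numeric(n)
  for (j in seq_len(n)) {
    u[j] <- sum(hidden * W2[, j])
  }
  exp(u) / sum(exp(u))
}

# Exhaustive pairwise concordance: P(score_pos > score_neg) + 0.5 P(tie).
oracle_concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# L2-penalised logistic objective written out directly (bias unpenalised).
oracle_logreg_objective <- function(w, b, X, y, C = 1) {
  z <- drop(X %*% w) + b
  p <- 1 / (1 + exp(-z))
  -sum(y * log(p) + (1 - y) * log(1 - p)) + sum(w^2) / (2 * C)
}

# Independent convex fit: generic BFGS on the objective above.
oracle_logreg_fit <- function(X, y, C = 1) {
  p <- ncol(X)
  obj <- function(par) oracle_logreg_objective(par[seq_len(p)], par[p + 1], X, y, C)
  fit <- stats::optim(rep(0, p + 1), obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1], objective = fit$value)
}

# Central finite differences of a scalar function of a matrix entry.
fd_gradient <- function(f, M, eps = 1e-6) {
  G <- M
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      up <- M; up[i, j] <- up[i, j] + eps
      dn <- M; dn[i, j] <- dn[i, j] - eps
      G[i, j] <- (f(up) - f(dn)) / (2 * eps)
    }
  }
  G
}

# Hand-set 4-token, size-2 embedding with small integer weights, used by
# the forward/loss/gradient checks.
toy_model_4 <- function() {
  W1 <- matrix(c(1, -1, 2, 0,
                 0, 1, -1, 1) / 2, nrow = 4, ncol = 2)
  rownames(W1) <- c("a", "r", "b", "c")
  W2 <- matrix(c(1, 0, -1, 1, 0, 2, 1, -1) / 2, nrow = 2, ncol = 4,
               dimnames = list(NULL, rownames(W1)))
  mk_embedding(W1, W2)
}

# Assemble an adr_embedding around explicit weight matrices.
mk_embedding <- function(W1, W2 = NULL) {
  if (is.null(W2)) {
    W2 <- matrix(0, nrow = ncol(W1), ncol = nrow(W1),
                 dimnames = list(NULL, rownames(W1)))
  }
  structure(
    list(W1 = W1, W2 = W2, vocabulary = rownames(W1), size = ncol(W1),
         iters = 0, mode = "full_softmax", seed = 0, epoch_loss = numeric(0)),
    class = "adr_embedding"
  )
}

# Assemble an adr_classifier with given parameters.
mk_classifier <- function(w, b) {
  structure(
    list(w = w, b = b, C = 1, max_iter = NA_integer_, size = length(w),
         objective = NA_real_, converged = NA, n_train = NA_integer_,
         seed = NA_integer_),
    class = "adr_classifier"
  )
}

# Three-triple toy knowledge graph used across embedding tests.
toy_kg_3 <- function() {
  kg_build(tibble::tibble(
    head = c("D1", "D1", "D2"),
    relation = c("has_side_effect", "has_target", "has_side_effect"),
    tail = c("S1", "T1", "S2")
  ))
}

# A small but non-trivial signal graph for pipeline-level unit tests.
small_signal_kg <- function(seed = 1) {
  synth_kg(n_drugs = 60, n_side_effects = 60, n_targets = 30,
           n_indications = 40, n_clusters = 3, p_in = 0.4, p_out = 0.02,
           seed = seed)
}
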