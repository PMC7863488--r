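sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable log(1 + exp(z)).
log1pexp <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))

#' Feature vector of a drug/ADR candidate pair
#'
#' The classifier input is the difference between the candidate attribute's
#' embedding vector and the drug's embedding vector, `x_adr - x_drug`.
#'
#' @param drug_vec,adr_vec Numeric vectors of equal length.
#' @return `adr_vec - drug_vec`.
#' @export
feature_vector <- function(drug_vec, adr_vec) {
  if (length(drug_vec) != length(adr_vec)) {
    stop("drug and ADR vectors differ in length", call. = FALSE)
  }
  adr_vec - drug_vec
}

# Feature matrix for a pair table: one row per pair, x_attr - x_drug.
feature_matrix <- function(embedding, pairs) {
  stopifnot(inherits(embedding, "adr_embedding"))
  attr_col <- if ("attribute" %in% names(pairs)) "attribute" else "adr"
  tokens <- unique(c(pairs$drug, pairs[[attr_col]]))
  missing <- setdiff(tokens, embedding$vocabulary)
  if (length(missing) > 0) {
    stop("no embedding vector for: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  }
  embedding$W1[match(pairs[[attr_col]], embedding$vocabulary), , drop = FALSE] -
    embedding$W1[match(pairs$drug, embedding$vocabulary), , drop = FALSE]
}

#' Fit the logistic-regression ADR link classifier
#'
#' Minimises the summed binary cross-entropy over the labelled training
#' pairs plus an L2 penalty `||w||^2 / (2C)` on the weights (bias
#' unpenalised), using L-BFGS-B on the explicit convex objective with
#' analytic gradients. Features are the embedding differences
#' `x_attribute - x_drug`; replicated negative rows weight the objective by
#' their multiplicity exactly as duplicated rows would.
#'
#' @param train_pairs Tibble with columns `drug`, `attribute`, `label`
#'   (0/1); both classes must be present. Duplicate rows are legitimate
#'   (replicated negatives) and act as weights.
#' @param embedding An `adr_embedding` covering every token in
#'   `train_pairs`.
#' @param C Inverse regularisation strength (default 1).
#' @param max_iter Maximum optimiser iterations (default 10000).
#' @param seed Kept for interface symmetry and recorded in the model; the
#'   fit itself is deterministic (zero initialisation, deterministic
#'   optimiser).
#' @param collapse_duplicates When TRUE, identical rows are collapsed into
#'   case weights before optimisation; the objective (and hence the fit) is
#'   identical, only faster.
#' @return An `adr_classifier`: weight vector `w`, bias `b`, settings and
#'   the achieved objective value.
#' @export
fit_adr_classifier <- function(train_pairs, embedding, C = 1,
                               max_iter = 10000, seed = 1,
                               collapse_duplicates = FALSE) {
  stopifnot(nrow(train_pairs) > 0, C > 0, max_iter >= 1)
  y <- as.numeric(train_pairs$label)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training pairs contain a single class", call. = FALSE)
  }

  if (collapse_duplicates) {
    grouped <- train_pairs |>
      dplyr::count(.data$drug, .data$attribute, .data$label, name = "weight")
    X <- feature_matrix(embedding, grouped)
    y <- as.numeric(grouped$label)
    wts <- grouped$weight
  } else {
    X <- feature_matrix(embedding, train_pairs)
    wts <- rep(1, length(y))
  }
  p <- ncol(X)

  objective <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    z <- drop(X %*% w) + b
    sum(wts * (log1pexp(z) - y * z)) + sum(w^2) / (2 * C)
  }
  gradient <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    z <- drop(X %*% w) + b
    r <- wts * (sigmoid(z) - y)
    c(drop(crossprod(X, r)) + w / C, sum(r))
  }

  opt <- stats::optim(rep(0, p + 1), objective, gradient, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e2))

  structure(
    list(w = opt$par[seq_len(p)], b = opt$par[p + 1], C = C,
         max_iter = max_iter, size = p, objective = opt$value,
         converged = opt$convergence == 0, n_train = nrow(train_pairs),
         seed = seed),
    class = "adr_classifier"
  )
}

#' Predicted link probability for feature vectors
#'
#' The standard logistic link `sigmoid(w . x + b)` applied to one feature
#' vector or to the rows of a feature matrix.
#'
#' @param model An `adr_classifier`.
#' @param feature Numeric vector of length `size`, or a matrix with `size`
#'   columns.
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
predict_probability <- function(model, feature) {
  stopifnot(inherits(model, "adr_classifier"))
  if (is.matrix(feature)) {
    if (ncol(feature) != model$size) stop("feature length mismatch", call. = FALSE)
    z <- drop(feature %*% model$w) + model$b
  } else {
    if (length(feature) != model$size) stop("feature length mismatch", call. = FALSE)
    z <- sum(model$w * feature) + model$b
  }
  if (any(!is.finite(z))) stop("non-finite feature input", call. = FALSE)
  sigmoid(z)
}

#' Score drug/attribute pairs
#'
#' @param model An `adr_classifier`.
#' @param embedding An `adr_embedding` covering all tokens.
#' @param pairs Tibble with columns `drug` and `attribute` (or `adr`).
#' @return A tibble `drug`, `adr`, `probability`, one row per input pair in
#'   input order.
#' @export
score_pairs <- function(model, embedding, pairs) {
  attr_col <- if ("attribute" %in% names(pairs)) "attribute" else "adr"
  out <- tibble::tibble(drug = pairs$drug, adr = pairs[[attr_col]])
  out$probability <- if (nrow(pairs) == 0) numeric(0) else
    as.numeric(predict_probability(model, feature_matrix(embedding, pairs)))
  out
}

#' Rank drugs by predicted probability of an ADR
#'
#' Scores every drug against one ADR and orders the result by descending
#' probability, ties broken by lexicographic drug id so the ranking is
#' deterministic.
#'
#' @param model An `adr_classifier`.
#' @param embedding An `adr_embedding`.
#' @param adr The ADR token to score against.
#' @param drugs Character vector of drug ids to rank.
#' @param top_n Optional; keep only the first `top_n` rows.
#' @return A tibble `drug`, `adr`, `probability` in rank order.
#' @export
rank_drugs_for_adr <- function(model, embedding, adr, drugs, top_n = NULL) {
  stopifnot(length(adr) == 1, length(drugs) > 0)
  if (!adr %in% embedding$vocabulary) {
    stop("unknown ADR token: ", adr, call. = FALSE)
  }
  scored <- score_pairs(model, embedding,
                        tibble::tibble(drug = drugs, attribute = adr))
  scored <- dplyr::arrange(scored, dplyr::desc(.data$probability), .data$drug)
  if (!is.null(top_n)) scored <- utils::head(scored, top_n)
  scored
}

#' Mean predicted probability per drug group
#'
#' Averages prediction probabilities within externally supplied drug groups
#' (e.g. annotation classes of liver-injury concern); used for case-study
#' style comparisons of group-level risk.
#'
#' @param predictions A tibble from [score_pairs()] (columns `drug`,
#'   `probability`).
#' @param grouping Drug-to-group map: a named character vector (names are
#'   drug ids) or a tibble with columns `drug` and `group`. Every predicted
#'   drug must be mapped.
#' @return A tibble `group`, `n`, `mean_probability`, one row per group
#'   with at least one member.
#' @export
group_mean_probability <- function(predictions, grouping) {
  if (is.character(grouping) && !is.null(names(grouping))) {
    grouping <- tibble::tibble(drug = names(grouping), group = unname(grouping))
  }
  grouping <- tibble::as_tibble(grouping)
  stopifnot(all(c("drug", "group") %in% names(grouping)))
  unmapped <- setdiff(unique(predictions$drug), grouping$drug)
  if (length(unmapped) > 0) {
    stop("drug(s) missing from grouping: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  predictions |>
    dplyr::inner_join(grouping, by = "drug") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_probability = mean(.data$probability),
                     .groups = "drop")
}

#' Write predictions as CSV
#'
#' Columns `drug_id`, `adr_id`, `probability` (six decimal places).
#'
#' @param predictions A tibble from [score_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
predictions_write <- function(predictions, path) {
  out <- tibble::tibble(
    drug_id = predictions$drug,
    adr_id = predictions$adr,
    probability = sprintf("%.6f", predictions$probability)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Persist a classifier as a small text artifact
#'
#' Line 1: `size C b`, then one weight coordinate per line.
#'
#' @param model An `adr_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "adr_classifier"))
  readr::write_lines(
    c(paste(model$size, format(model$C, digits = 17),
            format(model$b, digits = 17)),
      format(model$w, digits = 17)),
    path
  )
  invisible(path)
}

#' Read a classifier text artifact
#' @param path Path written by [write_classifier()].
#' @return An `adr_classifier` (objective/convergence fields NA).
#' @export
read_classifier <- function(path) {
  lines <- readr::read_lines(path)
  header <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(header) != 3) stop("malformed classifier header", call. = FALSE)
  w <- as.numeric(lines[-1])
  if (length(w) != header[1] || anyNA(w)) {
    stop("classifier weight count does not match declared size", call. = FALSE)
  }
  structure(
    list(w = w, b = header[3], C = header[2], max_iter = NA_integer_,
         size = as.integer(header[1]), objective = NA_real_, converged = NA,
         n_train = NA_integer_, seed = NA_integer_),
    class = "adr_classifier"
  )
}

#' @export
print.adr_classifier <- function(x, ...) {
  cat("<adr_classifier> size", x$size, ", C =", x$C,
      ", objective", format(x$objective, digits = 6),
      if (isTRUE(x$converged)) "(converged)" else "", "\n")
  invisible(x)
}

#' Tidy classifier coefficients
#'
#' @param x An `adr_classifier`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`: the bias followed by each weight
#'   coordinate `d1 ... d<size>`.
#' @export
tidy.adr_classifier <- function(x, ...) {
  tibble::tibble(
    term = c("(bias)", paste0("d", seq_len(x$size))),
    estimate = c(x$b, x$w)
  )
}

#' One-row classifier summary
#'
#' @param x An `adr_classifier`.
#' @param ... Unused.
#' @return A tibble with size, regularisation, objective value, convergence
#'   flag and training-row count.
#' @export
glance.adr_classifier <- function(x, ...) {
  tibble::tibble(
    size = x$size, C = x$C, max_iter = x$max_iter,
    objective = x$objective, converged = x$converged, n_train = x$n_train
  )
}
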