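#' Default end-to-end run configuration
#'
#' Mirrors the method's stated operating point: embedding dimension 800,
#' 2500 training epochs, CBOW-style context window spanning the whole
#' 3-token sentence, all tokens kept, logistic regression at C = 1 with at
#' most 10000 solver iterations, 10% indication holdout with 10x replicated
#' training negatives, classification threshold 0.5.
#'
#' @return Named list of defaults, overridable per call in
#'   [run_experiment()], [run_sweep()] and the command-line interface.
#' @export
default_config <- function() {
  list(
    size = 800, iters = 2500, mode = "full_softmax",
    lr_initial = 0.025, lr_final = 1e-4, negative = 5,
    holdout_frac = 0.1, replication = 10,
    C = 1, max_iter = 10000, threshold = 0.5
  )
}

merge_config <- function(...) {
  override <- list(...)
  cfg <- default_config()
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(override)] <- override
  cfg
}

#' Read a flat key = value run-configuration file
#'
#' Lines of the form `key = value` (or `key value`); `#` starts a comment.
#' Unknown keys are errors; missing keys take the [default_config()] value.
#'
#' @param path Path to the config file.
#' @return Full configuration list.
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*|\\s+")
  if (any(lengths(kv) != 2)) stop("malformed config line", call. = FALSE)
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- lapply(kv, function(x) {
    v <- utils::type.convert(x[[2]], as.is = TRUE)
    v
  })
  do.call(merge_config, stats::setNames(vals, keys))
}

# One complete pipeline pass: split -> embed -> fit -> evaluate. Test pairs
# whose tokens lost every corpus edge to the holdout (and hence have no
# embedding) are dropped with a warning.
run_pipeline_once <- function(kg, seed, cfg) {
  split <- make_split(kg, holdout_frac = cfg$holdout_frac,
                      replication = cfg$replication, seed = seed)
  corpus <- build_corpus(split$corpus)
  embedding <- train_embedding(
    corpus, size = cfg$size, iters = cfg$iters, mode = cfg$mode,
    lr_initial = cfg$lr_initial, lr_final = cfg$lr_final,
    negative = cfg$negative, seed = child_seed(seed, 3)
  )
  finish_pipeline(split, embedding, cfg, seed)
}

finish_pipeline <- function(split, embedding, cfg, seed) {
  classifier <- fit_adr_classifier(
    split$train_pairs, embedding, C = cfg$C, max_iter = cfg$max_iter,
    seed = child_seed(seed, 4), collapse_duplicates = TRUE
  )
  report <- evaluate_holdout(classifier, embedding, split$test_pairs,
                             threshold = cfg$threshold)
  list(split = split, embedding = embedding, classifier = classifier,
       report = report)
}

#' Evaluate a classifier on held-out labelled pairs
#'
#' Scores the test pairs and computes the full evaluation report. Pairs
#' whose drug or attribute has no embedding vector (possible when the
#' holdout removed an entity's only corpus edge) are dropped with a
#' warning. Usable standalone on persisted artifacts: evaluation does not
#' retrain anything.
#'
#' @param classifier An `adr_classifier`.
#' @param embedding An `adr_embedding`.
#' @param test_pairs Tibble `drug`, `attribute`, `label`.
#' @param threshold Classification threshold (default 0.5).
#' @return An `adr_eval`.
#' @export
evaluate_holdout <- function(classifier, embedding, test_pairs,
                             threshold = 0.5) {
  known <- test_pairs$drug %in% embedding$vocabulary &
    test_pairs$attribute %in% embedding$vocabulary
  if (!all(known)) {
    warning(sprintf("dropping %d test pair(s) with unembedded tokens",
                    sum(!known)), call. = FALSE)
    test_pairs <- test_pairs[known, ]
  }
  preds <- score_pairs(classifier, embedding, test_pairs)
  evaluate_predictions(preds$probability, test_pairs$label,
                       threshold = threshold)
}

#' Run the repeated end-to-end experiment
#'
#' For each repeat r, derives seed `seed + r`, re-splits the graph,
#' re-embeds the corpus from scratch, re-fits the classifier and evaluates
#' on the fresh held-out pairs — every stage independent across repeats.
#' The result mirrors the usual repeated-experiment table: one row per
#' repeat plus an arithmetic-mean row.
#'
#' @param kg An `adr_kg` (conflicts are excluded first).
#' @param n_repeats Number of independent repeats (>= 1; the reference
#'   protocol uses 6).
#' @param seed Master seed; repeat r uses `seed + r`.
#' @param ... Configuration overrides, see [default_config()].
#' @return An `adr_experiment` tibble with columns `experiment`
#'   (`"1"..."n"` and `"mean"`), `auc`, `precision`, `recall`, `f_score`,
#'   `n_test`; the per-repeat `adr_eval` reports are attached as attribute
#'   `"reports"`.
#' @examples
#' \donttest{
#' g <- synth_kg(seed = 1)
#' run_experiment(g$kg, n_repeats = 2, seed = 1, size = 32, iters = 100)
#' }
#' @export
run_experiment <- function(kg, n_repeats = 6, seed = 1, ...) {
  stopifnot(inherits(kg, "adr_kg"), n_repeats >= 1)
  cfg <- merge_config(...)
  kg <- exclude_conflicts(kg)$kg
  reports <- purrr::map(seq_len(n_repeats), function(r) {
    run_pipeline_once(kg, seed + r, cfg)$report
  })
  rows <- purrr::map_dfr(reports, glance)
  out <- dplyr::bind_cols(
    tibble::tibble(experiment = as.character(seq_len(n_repeats))),
    rows[, c("auc", "precision", "recall", "f_score", "n")]
  ) |> dplyr::rename(n_test = "n")
  mean_row <- dplyr::summarise(
    out, experiment = "mean",
    dplyr::across(c("auc", "precision", "recall", "f_score"), mean),
    n_test = sum(.data$n_test)
  )
  out <- dplyr::bind_rows(out, mean_row)
  attr(out, "reports") <- reports
  class(out) <- c("adr_experiment", class(out))
  out
}

#' Sweep embedding iterations and dimensions
#'
#' Evaluates held-out prediction performance over a grid of embedding
#' epoch counts and vector sizes. The split (and hence the test set) is
#' fixed across all grid cells so only the embedding parameters vary.
#'
#' @param kg An `adr_kg`.
#' @param iters_grid Integer vector of embedding epoch counts.
#' @param sizes Integer vector of embedding dimensions.
#' @param seed Master seed (fixed split; embedding seed shared across
#'   cells).
#' @param ... Configuration overrides, see [default_config()].
#' @return An `adr_sweep` tibble with columns `iters`, `size`, `auc`,
#'   `precision`, `recall`, `f_score`, one row per grid cell.
#' @export
run_sweep <- function(kg, iters_grid, sizes, seed = 1, ...) {
  stopifnot(inherits(kg, "adr_kg"), length(iters_grid) >= 1,
            length(sizes) >= 1)
  cfg <- merge_config(...)
  kg <- exclude_conflicts(kg)$kg
  split <- make_split(kg, holdout_frac = cfg$holdout_frac,
                      replication = cfg$replication, seed = seed)
  corpus <- build_corpus(split$corpus)
  grid <- tidyr::expand_grid(iters = iters_grid, size = sizes)
  rows <- purrr::pmap_dfr(grid, function(iters, size) {
    cell_cfg <- cfg
    cell_cfg$iters <- iters
    cell_cfg$size <- size
    embedding <- train_embedding(
      corpus, size = size, iters = iters, mode = cfg$mode,
      lr_initial = cfg$lr_initial, lr_final = cfg$lr_final,
      negative = cfg$negative, seed = child_seed(seed, 3)
    )
    res <- finish_pipeline(split, embedding, cell_cfg, seed)
    dplyr::bind_cols(tibble::tibble(iters = iters, size = size),
                     glance(res$report)[, c("auc", "precision", "recall",
                                            "f_score")])
  })
  class(rows) <- c("adr_sweep", class(rows))
  rows
}

#' Plot a parameter sweep
#'
#' @param object An `adr_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot of held-out AUC against embedding epochs, one line per
#'   vector size.
#' @export
autoplot.adr_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$iters, y = .data$auc,
                               colour = factor(.data$size),
                               group = factor(.data$size))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "embedding epochs", y = "held-out AUC",
                  colour = "size")
}

#' Train on the full graph and rank every drug for one ADR
#'
#' Embeds the complete (conflict-cleaned) graph, fits the classifier on all
#' labelled pairs and ranks every drug by its predicted probability of the
#' given ADR in descending order — the screening use of the method, where
#' no holdout is wanted because every known edge should inform the ranking.
#'
#' @param kg An `adr_kg`.
#' @param adr ADR entity id to rank against.
#' @param top_n Optional; keep the `top_n` highest-probability drugs.
#' @param seed Master seed.
#' @param ... Configuration overrides, see [default_config()].
#' @return A tibble `drug`, `adr`, `probability` in rank order.
#' @export
run_rank <- function(kg, adr, top_n = NULL, seed = 1, ...) {
  stopifnot(inherits(kg, "adr_kg"))
  cfg <- merge_config(...)
  kg <- exclude_conflicts(kg)$kg
  if (!adr %in% kg$vocabulary) stop("unknown ADR token: ", adr, call. = FALSE)
  corpus <- build_corpus(kg)
  embedding <- train_embedding(
    corpus, size = cfg$size, iters = cfg$iters, mode = cfg$mode,
    lr_initial = cfg$lr_initial, lr_final = cfg$lr_final,
    negative = cfg$negative, seed = child_seed(seed, 3)
  )
  ind <- dplyr::filter(kg$triples, .data$relation == "has_indication")
  se <- dplyr::filter(kg$triples, .data$relation == "has_side_effect")
  train_pairs <- dplyr::bind_rows(
    tibble::tibble(drug = se$head, attribute = se$tail, label = 1L),
    tibble::tibble(drug = rep(ind$head, cfg$replication),
                   attribute = rep(ind$tail, cfg$replication), label = 0L)
  )
  classifier <- fit_adr_classifier(train_pairs, embedding, C = cfg$C,
                                   max_iter = cfg$max_iter,
                                   seed = child_seed(seed, 4),
                                   collapse_duplicates = TRUE)
  rank_drugs_for_adr(classifier, embedding, adr,
                     drugs = kg_entities(kg, "drug"), top_n = top_n)
}
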