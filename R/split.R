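#' Remove indication edges that contradict a side-effect edge
#'
#' An indication of a drug cannot simultaneously be a side effect of that
#' same drug, and the split protocol treats drug-indication pairs as the
#' negative class. Any (drug, attribute) pair asserted under both
#' `has_indication` and `has_side_effect` therefore has its indication edge
#' dropped (the side-effect edge, the safety-relevant one, is kept). The
#' same attribute appearing as an indication of one drug and a side effect
#' of a different drug is not a conflict.
#'
#' @param kg An `adr_kg` object.
#' @return A list with `kg` (the cleaned graph) and `removed` (tibble of the
#'   dropped `head`, `tail` pairs; zero rows when conflict-free).
#' @export
exclude_conflicts <- function(kg) {
  stopifnot(inherits(kg, "adr_kg"))
  ind <- dplyr::filter(kg$triples, .data$relation == "has_indication")
  se <- dplyr::filter(kg$triples, .data$relation == "has_side_effect")
  removed <- dplyr::inner_join(ind[, c("head", "tail")],
                               se[, c("head", "tail")],
                               by = c("head", "tail"))
  if (nrow(removed) == 0) {
    return(list(kg = kg, removed = removed))
  }
  warning(sprintf(
    "%d drug-attribute pair(s) asserted as both indication and side effect; dropping the indication edge(s)",
    nrow(removed)), call. = FALSE)
  keep <- dplyr::anti_join(
    kg$triples,
    dplyr::mutate(removed, relation = "has_indication"),
    by = c("head", "relation", "tail")
  )
  list(kg = kg_build(keep, kinds = kg$entities), removed = removed)
}

#' Split a knowledge graph into embedding corpus and classifier sets
#'
#' Implements the holdout protocol: a fraction (`floor(holdout_frac *
#' n_indication_pairs)`, default 10%) of the drug-indication pairs is drawn
#' uniformly without replacement as test negatives, an equal number of
#' drug-side-effect pairs as test positives. Both held-out sets are removed
#' from the embedding corpus (drug-target triples are always retained) and
#' never appear in classifier training, simulating unknown ADRs. The
#' classifier training set is the retained side-effect pairs (label 1) plus
#' the retained indication pairs each copied `replication` times (label 0)
#' to counter the class imbalance.
#'
#' The negative and positive draws use separate random streams derived from
#' `seed`, so changing one sample size does not perturb the other draw.
#'
#' @param kg An `adr_kg`; run [exclude_conflicts()] first if the source data
#'   may contain indication/side-effect contradictions.
#' @param holdout_frac Fraction of indication pairs held out (0 < frac < 1).
#' @param replication Copy count for training negatives (default 10).
#' @param seed Integer seed; the split is deterministic given it.
#' @return An `adr_split`: list with `corpus` (an `adr_kg` of the retained
#'   triples), `train_pairs` and `test_pairs` (tibbles of `drug`,
#'   `attribute`, `label`), and the split settings.
#' @examples
#' g <- synth_kg(n_drugs = 30, n_side_effects = 30, n_targets = 10,
#'               n_indications = 20, seed = 1)
#' sp <- make_split(g$kg, seed = 1)
#' split_accounting(sp)
#' @export
make_split <- function(kg, holdout_frac = 0.1, replication = 10, seed = 1) {
  stopifnot(inherits(kg, "adr_kg"), holdout_frac > 0, holdout_frac < 1,
            replication >= 1)
  ind <- dplyr::filter(kg$triples, .data$relation == "has_indication")
  se <- dplyr::filter(kg$triples, .data$relation == "has_side_effect")
  if (nrow(ind) < 1) stop("no has_indication triples to hold out", call. = FALSE)

  n_hold <- floor(holdout_frac * nrow(ind))
  if (n_hold < 1) stop("holdout too small: no indication pairs selected",
                       call. = FALSE)
  if (nrow(se) < n_hold) {
    stop(sprintf("need %d side-effect pairs for test positives, have %d",
                 n_hold, nrow(se)), call. = FALSE)
  }

  with_seed(child_seed(seed, 1), neg_idx <- sample.int(nrow(ind), n_hold))
  with_seed(child_seed(seed, 2), pos_idx <- sample.int(nrow(se), n_hold))

  test_neg <- ind[neg_idx, ]
  test_pos <- se[pos_idx, ]
  ind_keep <- ind[-neg_idx, ]
  se_keep <- se[-pos_idx, ]

  held_out <- dplyr::bind_rows(test_neg, test_pos)
  retained <- dplyr::anti_join(kg$triples, held_out,
                               by = c("head", "relation", "tail"))
  corpus_kg <- kg_build(retained, kinds = kg$entities)

  train_pairs <- dplyr::bind_rows(
    tibble::tibble(drug = se_keep$head, attribute = se_keep$tail, label = 1L),
    tibble::tibble(
      drug = rep(ind_keep$head, times = replication),
      attribute = rep(ind_keep$tail, times = replication),
      label = 0L
    )
  )
  test_pairs <- dplyr::bind_rows(
    tibble::tibble(drug = test_pos$head, attribute = test_pos$tail, label = 1L),
    tibble::tibble(drug = test_neg$head, attribute = test_neg$tail, label = 0L)
  )

  structure(
    list(corpus = corpus_kg, train_pairs = train_pairs,
         test_pairs = test_pairs, holdout_frac = holdout_frac,
         replication = replication, seed = seed,
         n_holdout = n_hold,
         n_indication = nrow(ind), n_side_effect = nrow(se),
         n_target = sum(kg$triples$relation == "has_target")),
    class = "adr_split"
  )
}

#' Per-relation accounting of a split
#'
#' @param split An `adr_split` from [make_split()].
#' @return A tibble with one row per relation giving the number of pairs in
#'   the embedding corpus, classifier training rows (negatives counted with
#'   their replication), classifier test rows, and the original totals.
#' @export
split_accounting <- function(split) {
  stopifnot(inherits(split, "adr_split"))
  rc <- relation_counts(split$corpus)
  emb <- stats::setNames(rc$n[1:3], rc$relation[1:3])
  tibble::tibble(
    relation = KG_RELATIONS,
    embedding = as.integer(emb[KG_RELATIONS]),
    training = c(0L,
                 as.integer(emb[["has_indication"]]) * split$replication,
                 as.integer(emb[["has_side_effect"]])),
    testing = c(0L, split$n_holdout, split$n_holdout),
    total = c(split$n_target, split$n_indication, split$n_side_effect)
  )
}

#' Write a split to disk as its TSV manifest
#'
#' Emits the embedding-corpus triples, the labelled train pairs and the
#' labelled test pairs as TSV files plus a small JSON metadata file with the
#' split settings and counts.
#'
#' @param split An `adr_split`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
split_write <- function(split, dir) {
  stopifnot(inherits(split, "adr_split"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kg_write(split$corpus, file.path(dir, "corpus_triples.tsv"))
  readr::write_tsv(split$train_pairs, file.path(dir, "train_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(split$test_pairs, file.path(dir, "test_pairs.tsv"),
                   progress = FALSE)
  meta <- list(
    holdout_frac = split$holdout_frac, replication = split$replication,
    seed = split$seed, n_holdout = split$n_holdout,
    n_indication = split$n_indication, n_side_effect = split$n_side_effect,
    n_target = split$n_target
  )
  jsonlite::write_json(meta, file.path(dir, "split_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.adr_split <- function(x, ...) {
  cat("<adr_split> holdout", x$n_holdout, "per class (frac",
      x$holdout_frac, "), replication", x$replication, "\n")
  cat("  train pairs:", nrow(x$train_pairs),
      "(", sum(x$train_pairs$label == 1), "pos /",
      sum(x$train_pairs$label == 0), "neg rows )\n")
  cat("  test pairs: ", nrow(x$test_pairs), "\n")
  invisible(x)
}
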