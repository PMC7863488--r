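# Synthetic knowledge graphs with planted block structure.
#
# Drugs and attributes (side effects, targets, indications) are assigned
# round-robin to latent clusters; a drug-attribute edge is drawn with
# probability p_in when the two share a cluster and p_out otherwise. All
# three attribute types share the drug clustering, so targets and
# indications carry side-effect-relevant signal: the premise that shared
# attributes inform ADRs, in a form with analytic edge-count expectations.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-purpose child seeds (Lehmer step, kept < 2^31).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483647)
}

round_robin <- function(n, n_clusters) ((seq_len(n) - 1L) %% n_clusters) + 1L

# Edge probability matrix for one relation over drugs x attributes:
# within-leaning pairs follow the block model (p_in same cluster, p_out
# cross), pairs on off-leaning attributes are suppressed to p_out^2/p_in.
# The geometric form makes every entry collapse to p when p_in = p_out.
leaning_prob <- function(drug_cl, attr_cl, attr_on_leaning, p_in, p_out) {
  same <- outer(drug_cl, attr_cl, `==`)
  p_cross_type <- if (p_in > 0) p_out^2 / p_in else 0
  p <- matrix(p_cross_type, nrow = length(drug_cl), ncol = length(attr_cl))
  p[, attr_on_leaning] <- ifelse(same[, attr_on_leaning, drop = FALSE],
                                 p_in, p_out)
  p
}

sample_edges <- function(drugs, attrs, p) {
  hit <- which(matrix(stats::runif(length(p)) < p, nrow = length(drugs)),
               arr.ind = TRUE)
  tibble::tibble(head = drugs[hit[, 1]], tail = attrs[hit[, 2]])
}

block_edges <- function(drugs, attrs, drug_cl, attr_cl, p_in, p_out) {
  same <- outer(drug_cl, attr_cl, `==`)
  sample_edges(drugs, attrs, ifelse(same, p_in, p_out))
}

#' Generate a synthetic knowledge graph with planted cluster signal
#'
#' Emulates the shape of a drug/side-effect/target/indication knowledge
#' graph. Side effects and indications are conditions drawn from one shared
#' medical vocabulary, as in real label data where the same concept can be
#' a side effect of one drug and an indication of another: `n_side_effects`
#' conditions lean side-effect, `n_indications` lean indication. Entities
#' are assigned round-robin to `n_clusters` latent clusters. Edges are
#' drawn independently per drug-attribute pair:
#'
#' * on-leaning condition edges (side-effect edges to side-effect-leaning
#'   conditions, indication edges to indication-leaning conditions) and all
#'   drug-target edges follow the block model — probability `p_in` within a
#'   cluster, `p_out` across clusters;
#' * off-leaning condition edges (e.g. an indication edge to a
#'   side-effect-leaning condition) occur at the suppressed rate
#'   `p_out^2 / p_in`.
#'
#' The geometric suppression ties the type signal to the cluster signal:
#' when `p_in = p_out` every edge probability collapses to the common
#' value, so the null generator ([synth_kg_null()]) carries provably no
#' learnable structure. Any (drug, condition) pair sampled as both
#' indication and side effect has its indication edge dropped, since an
#' indication of a drug cannot be a side effect of the same drug.
#'
#' Defaults keep full-softmax embedding training tractable on one CPU while
#' leaving enough held-out pairs for stable evaluation.
#'
#' @param n_drugs,n_targets Entity counts for drugs and targets.
#' @param n_side_effects,n_indications Number of side-effect-leaning and
#'   indication-leaning conditions in the shared pool.
#' @param n_clusters Number of latent clusters (each count must be >= this).
#' @param p_in,p_out Within- and cross-cluster edge probabilities
#'   (`0 <= p_out <= p_in <= 1`).
#' @param seed Integer seed; the graph is a deterministic function of it.
#' @return A list with `kg` (an `adr_kg`) and `clusters` (tibble of
#'   `id`, `kind`, `cluster` for every entity, the planted ground truth;
#'   `kind` records each condition's leaning).
#' @examples
#' g <- synth_kg(n_drugs = 20, n_side_effects = 30, n_targets = 10,
#'               n_indications = 10, seed = 1)
#' relation_counts(g$kg)
#' @export
synth_kg <- function(n_drugs = 200, n_side_effects = 300, n_targets = 100,
                     n_indications = 100, n_clusters = 5,
                     p_in = 0.3, p_out = 0.02, seed = 1) {
  stopifnot(p_out >= 0, p_in >= p_out, p_in <= 1,
            min(n_drugs, n_side_effects, n_targets, n_indications) >= n_clusters)
  drugs <- sprintf("D%04d", seq_len(n_drugs))
  ses   <- sprintf("S%04d", seq_len(n_side_effects))
  inds  <- sprintf("I%04d", seq_len(n_indications))
  conds <- c(ses, inds)
  tgts  <- sprintf("T%04d", seq_len(n_targets))

  drug_cl <- round_robin(n_drugs, n_clusters)
  cond_cl <- round_robin(length(conds), n_clusters)
  tgt_cl  <- round_robin(n_targets, n_clusters)
  se_leaning <- seq_along(conds) <= n_side_effects

  p_se  <- leaning_prob(drug_cl, cond_cl, se_leaning, p_in, p_out)
  p_ind <- leaning_prob(drug_cl, cond_cl, !se_leaning, p_in, p_out)

  with_seed(seed, {
    se_edges  <- sample_edges(drugs, conds, p_se)
    tgt_edges <- block_edges(drugs, tgts, drug_cl, tgt_cl, p_in, p_out)
    ind_edges <- sample_edges(drugs, conds, p_ind)
  })

  triples <- dplyr::bind_rows(
    dplyr::mutate(se_edges, relation = "has_side_effect"),
    dplyr::mutate(tgt_edges, relation = "has_target"),
    dplyr::mutate(ind_edges, relation = "has_indication")
  )[, c("head", "relation", "tail")]

  kg <- kg_build(triples)
  # the shared condition pool can sample the same (drug, condition) pair
  # under both relations; the indication edge is dropped in that case
  suppressWarnings(kg <- exclude_conflicts(kg)$kg)

  clusters <- tibble::tibble(
    id = c(drugs, conds, tgts),
    kind = rep(c("drug", "side_effect", "indication", "target"),
               c(n_drugs, n_side_effects, n_indications, n_targets)),
    cluster = c(drug_cl, cond_cl, tgt_cl)
  )
  list(kg = kg, clusters = clusters)
}

#' Generate a null knowledge graph with no learnable signal
#'
#' Same procedure as [synth_kg()] with the within-cluster probability forced
#' equal to the cross-cluster probability, so edges carry no cluster signal.
#' Used to verify that the embedding-plus-classifier pipeline does not
#' hallucinate discrimination: its held-out AUC should sit near 0.5.
#'
#' @inheritParams synth_kg
#' @param p Common edge probability applied to every drug-attribute pair.
#' @return As [synth_kg()].
#' @export
synth_kg_null <- function(n_drugs = 200, n_side_effects = 300, n_targets = 100,
                          n_indications = 100, n_clusters = 5, p = 0.1,
                          seed = 1) {
  synth_kg(n_drugs, n_side_effects, n_targets, n_indications, n_clusters,
           p_in = p, p_out = p, seed = seed)
}

#' Generate a knowledge graph with exact per-relation pair counts
#'
#' Samples exactly the requested number of distinct (drug, attribute) pairs
#' per relation, uniformly over the bipartite grid. Attribute id spaces are
#' disjoint across kinds, so no indication/side-effect conflict can arise.
#' Useful for reproducing published dataset accounting (relationship
#' totals, holdout arithmetic) at full scale without any real database.
#'
#' @param n_drugs,n_side_effects,n_targets,n_indications Entity counts.
#' @param n_se,n_target,n_indication Number of distinct pairs per relation.
#' @param seed Integer seed.
#' @return An `adr_kg` object.
#' @export
synth_kg_counts <- function(n_drugs, n_side_effects, n_targets, n_indications,
                            n_se, n_target, n_indication, seed = 1) {
  stopifnot(n_se <= n_drugs * n_side_effects,
            n_target <= n_drugs * n_targets,
            n_indication <= n_drugs * n_indications)
  drugs <- sprintf("D%05d", seq_len(n_drugs))
  ses   <- sprintf("S%05d", seq_len(n_side_effects))
  tgts  <- sprintf("T%05d", seq_len(n_targets))
  inds  <- sprintf("I%05d", seq_len(n_indications))

  pair_sample <- function(rows, cols, k) {
    idx <- sample.int(length(rows) * as.numeric(length(cols)), k)
    tibble::tibble(head = rows[((idx - 1) %% length(rows)) + 1],
                   tail = cols[((idx - 1) %/% length(rows)) + 1])
  }

  with_seed(seed, {
    se_pairs  <- pair_sample(drugs, ses, n_se)
    tgt_pairs <- pair_sample(drugs, tgts, n_target)
    ind_pairs <- pair_sample(drugs, inds, n_indication)
  })

  triples <- dplyr::bind_rows(
    dplyr::mutate(se_pairs, relation = "has_side_effect"),
    dplyr::mutate(tgt_pairs, relation = "has_target"),
    dplyr::mutate(ind_pairs, relation = "has_indication")
  )[, c("head", "relation", "tail")]
  kg_build(triples)
}

#' Write a synthetic graph bundle to disk
#'
#' Emits the standard triple TSV and kind TSV of the triple store plus the
#' planted cluster ground truth as an `id<TAB>cluster` TSV.
#'
#' @param bundle A list as returned by [synth_kg()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
synth_kg_write <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kg_write(bundle$kg, file.path(dir, "triples.tsv"),
           kinds_path = file.path(dir, "kinds.tsv"))
  readr::write_tsv(bundle$clusters[, c("id", "cluster")],
                   file.path(dir, "clusters.tsv"), col_names = FALSE,
                   progress = FALSE)
  invisible(dir)
}
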