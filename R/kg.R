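#' @useDynLib adrkg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import tibble
NULL

# Relation vocabulary and the entity kind each relation's tail must carry.
KG_RELATIONS <- c("has_target", "has_indication", "has_side_effect")
KG_TAIL_KIND <- c(
  has_target      = "target",
  has_indication  = "indication",
  has_side_effect = "side_effect"
)
KG_KINDS <- c("drug", "side_effect", "target", "indication")

#' Construct a typed knowledge graph from a triple table
#'
#' Builds the typed triple store used throughout the package: drugs connected
#' to targets, indications and side effects by the relations `has_target`,
#' `has_indication` and `has_side_effect`. Duplicate triples are collapsed
#' (with a warning giving the count), entity kinds are inferred from the
#' relations (head is a drug, tail kind follows the relation) unless an
#' explicit kind map is supplied, and a deterministic token vocabulary is
#' assembled: the three relation tokens first, then entities in order of
#' first appearance (head before tail within a row).
#'
#' @param triples A data frame with character columns `head`, `relation`,
#'   `tail`. `relation` must be one of `has_target`, `has_indication`,
#'   `has_side_effect`.
#' @param kinds Optional entity kind map: a data frame with columns `id` and
#'   `kind`, or a named character vector (names are entity ids). Explicit
#'   kinds override inference; a conflict between an explicit kind and the
#'   kind implied by a triple is an error.
#' @return An object of class `adr_kg`: a list with `triples` (tibble),
#'   `entities` (tibble of `id`, `kind`; an attribute carried as both an
#'   indication and a side effect of different drugs gets one row per kind)
#'   and `vocabulary` (character vector of all tokens; its length is the
#'   vocabulary size n).
#' @examples
#' kg <- kg_build(tibble::tibble(
#'   head = c("D1", "D1"), relation = c("has_side_effect", "has_target"),
#'   tail = c("S1", "T1")
#' ))
#' kg_size(kg)
#' @export
kg_build <- function(triples, kinds = NULL) {
  triples <- tibble::as_tibble(triples)
  stopifnot(all(c("head", "relation", "tail") %in% names(triples)))
  triples <- dplyr::select(triples, "head", "relation", "tail") |>
    dplyr::mutate(dplyr::across(dplyr::everything(), as.character))

  bad_rel <- setdiff(unique(triples$relation), KG_RELATIONS)
  if (length(bad_rel) > 0) {
    stop("unknown relation(s): ", paste(bad_rel, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(triples$head)) || any(!nzchar(triples$tail))) {
    stop("entity ids must be non-empty strings", call. = FALSE)
  }

  n_before <- nrow(triples)
  triples <- dplyr::distinct(triples)
  n_dup <- n_before - nrow(triples)
  if (n_dup > 0) {
    warning(sprintf("collapsed %d duplicate triple(s)", n_dup), call. = FALSE)
  }

  # Kind inference: head -> drug, tail kind from the relation.
  inferred <- dplyr::bind_rows(
    tibble::tibble(id = triples$head, kind = "drug"),
    tibble::tibble(id = triples$tail, kind = unname(KG_TAIL_KIND[triples$relation]))
  ) |> dplyr::distinct()

  explicit <- normalize_kind_map(kinds)
  if (!is.null(explicit)) {
    inferred <- dplyr::distinct(dplyr::bind_rows(explicit, inferred))
  }

  # The same attribute id may legitimately be an indication of one drug and
  # a side effect of another (the per-drug contradiction is handled by
  # exclude_conflicts()); any other kind overlap is a validation error.
  dup_kind <- inferred |>
    dplyr::group_by(.data$id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(
      ok = all(.data$kind %in% c("indication", "side_effect")),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(dup_kind) > 0) {
    from_map <- !is.null(explicit) && any(dup_kind$id %in% explicit$id)
    stop(if (from_map) "entity kind conflict for: " else
           "entity asserted with two kinds: ",
         paste(utils::head(dup_kind$id, 5), collapse = ", "), call. = FALSE)
  }

  # Vocabulary: relation tokens eagerly first, then entities by first
  # appearance in row order (head before tail within a row).
  appearance <- unique(as.vector(rbind(triples$head, triples$tail)))
  vocabulary <- c(KG_RELATIONS, appearance)

  entities <- tibble::tibble(id = appearance) |>
    dplyr::left_join(inferred, by = "id",
                     relationship = "many-to-many")

  structure(
    list(triples = triples, entities = entities, vocabulary = vocabulary),
    class = "adr_kg"
  )
}

normalize_kind_map <- function(kinds) {
  if (is.null(kinds)) return(NULL)
  if (is.character(kinds) && !is.null(names(kinds))) {
    kinds <- tibble::tibble(id = names(kinds), kind = unname(kinds))
  }
  kinds <- tibble::as_tibble(kinds)
  stopifnot(all(c("id", "kind") %in% names(kinds)))
  bad <- setdiff(unique(kinds$kind), KG_KINDS)
  if (length(bad) > 0) {
    stop("unknown entity kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(kinds[, c("id", "kind")])
}

#' Read knowledge-graph triples from a TSV file
#'
#' Parses a UTF-8 tab-separated file with one `head<TAB>relation<TAB>tail`
#' triple per line. Lines starting with `#` and blank lines are skipped.
#' Duplicate lines are collapsed by [kg_build()].
#'
#' @param path Path to the triple file.
#' @param kinds Optional entity-kind map: a path to a two-column
#'   `id<TAB>kind` TSV, or anything accepted by the `kinds` argument of
#'   [kg_build()].
#' @return An `adr_kg` object.
#' @export
kg_read <- function(path, kinds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  arity <- lengths(fields)
  if (any(arity != 3)) {
    bad <- keep[which(arity != 3)[1]]
    stop(sprintf("malformed triple line %d: expected 3 tab-separated fields, got %d",
                 bad, arity[which(arity != 3)[1]]), call. = FALSE)
  }
  m <- if (length(fields) > 0) do.call(rbind, fields) else
    matrix(character(), ncol = 3)
  if (is.character(kinds) && length(kinds) == 1 && is.null(names(kinds))) {
    kinds <- kg_read_kinds(kinds)
  }
  kg_build(
    tibble::tibble(head = m[, 1], relation = m[, 2], tail = m[, 3]),
    kinds = kinds
  )
}

kg_read_kinds <- function(path) {
  readr::read_tsv(path, col_names = c("id", "kind"),
                  col_types = readr::cols(.default = readr::col_character()),
                  comment = "#", progress = FALSE)
}

#' Write knowledge-graph triples to a TSV file
#'
#' One triple per line, `head<TAB>relation<TAB>tail`. Reading the file back
#' with [kg_read()] reproduces the same triple set and vocabulary size.
#'
#' @param kg An `adr_kg` object.
#' @param path Output file path.
#' @param kinds_path Optional path; when given, the entity kind table is also
#'   written as an `id<TAB>kind` TSV.
#' @return `path`, invisibly.
#' @export
kg_write <- function(kg, path, kinds_path = NULL) {
  stopifnot(inherits(kg, "adr_kg"))
  readr::write_tsv(kg$triples, path, col_names = FALSE, progress = FALSE)
  if (!is.null(kinds_path)) {
    readr::write_tsv(kg$entities, kinds_path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Count triples per relation
#'
#' @param kg An `adr_kg` object.
#' @return A tibble with one row per relation (`has_target`,
#'   `has_indication`, `has_side_effect`, in that order) plus a `total` row;
#'   the per-relation counts always sum to the total.
#' @export
relation_counts <- function(kg) {
  stopifnot(inherits(kg, "adr_kg"))
  counts <- vapply(KG_RELATIONS, function(r) sum(kg$triples$relation == r),
                   integer(1))
  tibble::tibble(
    relation = c(KG_RELATIONS, "total"),
    n = unname(c(counts, sum(counts)))
  )
}

#' Vocabulary size of a knowledge graph
#'
#' Total number of tokens (entities plus relation tokens) — the `n` of the
#' embedding softmax.
#' @param kg An `adr_kg` object.
#' @return Integer vocabulary size.
#' @export
kg_size <- function(kg) {
  stopifnot(inherits(kg, "adr_kg"))
  length(kg$vocabulary)
}

#' Entities of a given kind
#' @param kg An `adr_kg` object.
#' @param kind One of `drug`, `side_effect`, `target`, `indication`.
#' @return Character vector of entity ids.
#' @export
kg_entities <- function(kg, kind = NULL) {
  stopifnot(inherits(kg, "adr_kg"))
  if (is.null(kind)) return(kg$entities$id)
  kind <- match.arg(kind, KG_KINDS)
  kg$entities$id[kg$entities$kind == kind]
}

#' @export
print.adr_kg <- function(x, ...) {
  counts <- relation_counts(x)
  cat("<adr_kg>", dplyr::n_distinct(x$entities$id), "entities,",
      counts$n[counts$relation == "total"], "triples,",
      "vocabulary size", length(x$vocabulary), "\n")
  kc <- dplyr::count(x$entities, .data$kind)
  cat("  entities: ", paste(sprintf("%s=%d", kc$kind, kc$n), collapse = ", "), "\n")
  cat("  triples:  ",
      paste(sprintf("%s=%d", counts$relation[1:3], counts$n[1:3]), collapse = ", "),
      "\n")
  invisible(x)
}
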