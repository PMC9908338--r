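# Four-relation medical knowledge graph: construction, validation, stats, IO.

#' Relation and category vocabulary of the medical knowledge graph
#'
#' The graph uses four typed relations: chief-complaint and symptom entities
#' point into the syndrome they were recorded with, and each syndrome points
#' to its disease-nature and disease-location labels.
#'
#' @format Character vectors `KG_RELATIONS` and `KG_CATEGORIES`.
#' @export
KG_RELATIONS <- c("chief_complaint_syndrome", "symptom_syndrome",
                  "syndrome_nature", "syndrome_location")

#' @rdname KG_RELATIONS
#' @export
KG_CATEGORIES <- c("symptom", "chief_complaint", "syndrome", "nature",
                   "location")

# head/tail category implied by each relation
REL_SCHEMA <- list(
  chief_complaint_syndrome = c(head = "chief_complaint", tail = "syndrome"),
  symptom_syndrome = c(head = "symptom", tail = "syndrome"),
  syndrome_nature = c(head = "syndrome", tail = "nature"),
  syndrome_location = c(head = "syndrome", tail = "location")
)

#' Construct a validated knowledge graph
#'
#' Checks that every triple uses a known relation, that both endpoints exist
#' in the entity vocabulary, and that endpoint categories agree with the
#' relation schema. Duplicate triples collapse (set semantics).
#'
#' @param entities Data frame with columns `entity_id`, `category`.
#' @param triples Data frame with columns `head`, `relation`, `tail`.
#' @param surface Optional named character map entity id -> surface form
#'   (defaults to the identity map).
#' @return A list of class `"kgraph"` with `entities`, `triples`, `surface`.
#' @export
kgraph <- function(entities, triples, surface = NULL) {
  entities <- unique(entities[, c("entity_id", "category")])
  if (anyDuplicated(entities$entity_id))
    stop("entity ids must be unique across categories")
  if (!all(entities$category %in% KG_CATEGORIES))
    stop("unknown entity category: ",
         paste(setdiff(entities$category, KG_CATEGORIES), collapse = ", "))
  triples <- unique(triples[, c("head", "relation", "tail")])
  if (nrow(triples)) {
    if (!all(triples$relation %in% KG_RELATIONS))
      stop("unknown relation: ",
           paste(setdiff(triples$relation, KG_RELATIONS), collapse = ", "))
    cat_of <- stats::setNames(entities$category, entities$entity_id)
    missing <- setdiff(c(triples$head, triples$tail), entities$entity_id)
    if (length(missing))
      stop("triple endpoints missing from vocabulary: ",
           paste(utils::head(missing, 5), collapse = ", "))
    for (rel in unique(triples$relation)) {
      sel <- triples$relation == rel
      sch <- REL_SCHEMA[[rel]]
      bad_h <- cat_of[triples$head[sel]] != sch[["head"]]
      bad_t <- cat_of[triples$tail[sel]] != sch[["tail"]]
      if (any(bad_h) || any(bad_t))
        stop(sprintf("category/relation mismatch for relation %s", rel))
    }
  }
  rownames(entities) <- NULL
  rownames(triples) <- NULL
  if (is.null(surface))
    surface <- stats::setNames(entities$entity_id, entities$entity_id)
  kg <- list(entities = entities, triples = triples, surface = surface)
  class(kg) <- "kgraph"
  kg
}

kg_surfaces <- function(kg) {
  s <- kg$surface %||% stats::setNames(kg$entities$entity_id,
                                       kg$entities$entity_id)
  s
}

entities_of_category <- function(kg, category) {
  kg$entities$entity_id[kg$entities$category == category]
}

#' Decompose a syndrome string into nature and location labels
#'
#' Every maximal lexicon substring (token run) of the syndrome string
#' contributes its label; a syndrome such as "damp-heat obstructing the
#' meridian" yields natures \{damp-heat, obstruction\} and location
#' \{meridians\} given lexicons carrying those surfaces. Empty results are
#' allowed and flagged with a warning, since under-described syndromes occur
#' in practice.
#'
#' @param syndrome Syndrome string.
#' @param nature_lexicon,location_lexicon Lexicons (data frame or named
#'   vector surface -> label id).
#' @return List with character vectors `natures` and `locations` (sorted,
#'   unique).
#' @export
decompose_syndrome <- function(syndrome, nature_lexicon, location_lexicon) {
  nat_lex <- as_lexicon(nature_lexicon)
  loc_lex <- as_lexicon(location_lexicon)
  if (nrow(nat_lex) == 0 || nrow(loc_lex) == 0)
    stop("lexicons must be non-empty")
  tokens <- tokenize_text(syndrome)
  hit <- function(lex) {
    m <- match_surfaces(tokens, unique(lex$surface))
    if (nrow(m) == 0) return(character(0))
    sort(unique(lex$entity_id[match(m$surface, lex$surface)]))
  }
  natures <- hit(nat_lex)
  locations <- hit(loc_lex)
  if (length(natures) == 0 && length(locations) == 0)
    warning(sprintf("syndrome '%s' matched no nature or location label",
                    syndrome))
  list(natures = natures, locations = locations)
}

#' Build the knowledge graph from parsed records
#'
#' For each record with a non-empty syndrome string, emits the four edge
#' kinds: (chief entity -> syndrome), (symptom entity -> syndrome),
#' (syndrome -> nature), (syndrome -> location). Chief entities come from
#' dictionary extraction over the chief complaint; symptom entities from
#' longest-match over the symptom fields. Duplicates across records collapse.
#' The syndrome entity id is the whitespace-normalized syndrome string.
#'
#' @param records List of `emr_record`s.
#' @param lexicons Named list of lexicons: `symptom`, `chief`, `nature`,
#'   `location` (as produced by [world_lexicons()]).
#' @param threshold Confidence threshold for chief-complaint extraction.
#' @param add_inverse Also materialize reversed chief/symptom edges
#'   (default `FALSE`; the stated edge direction points into the syndrome).
#' @return A `kgraph`.
#' @export
build_kg <- function(records, lexicons, threshold = 0.5,
                     add_inverse = FALSE) {
  stopifnot(all(c("symptom", "chief", "nature", "location") %in%
                  names(lexicons)))
  sym_lex <- as_lexicon(lexicons$symptom)
  chief_lex <- as_lexicon(lexicons$chief)
  ent <- list()
  tri <- list()
  surface <- character(0)
  add_ent <- function(ids, category, surfaces = NULL) {
    if (length(ids) == 0) return()
    ent[[length(ent) + 1L]] <<- data.frame(entity_id = ids,
                                           category = category,
                                           stringsAsFactors = FALSE)
    if (!is.null(surfaces)) surface[ids] <<- surfaces
  }
  add_tri <- function(h, r, t) {
    if (length(h) == 0 || length(t) == 0) return()
    tri[[length(tri) + 1L]] <<- expand.grid(head = h, relation = r, tail = t,
                                            stringsAsFactors = FALSE)
  }
  n_skipped <- 0L
  for (rec in records) {
    syn <- trimws(gsub("[[:space:]]+", " ", rec$syndrome %||% ""))
    if (!nzchar(syn)) {
      n_skipped <- n_skipped + 1L
      next
    }
    syn_id <- if (!is.null(rec$syndrome_id) && nzchar(rec$syndrome_id))
      rec$syndrome_id else syn
    add_ent(syn_id, "syndrome")
    labs <- decompose_syndrome(syn, lexicons$nature, lexicons$location)
    add_ent(labs$natures, "nature")
    add_ent(labs$locations, "location")
    add_tri(syn_id, "syndrome_nature", labs$natures)
    add_tri(syn_id, "syndrome_location", labs$locations)
    # symptom entities from the five text fields
    for (f in rec$symptom_fields) {
      toks <- tokenize_text(f)
      m <- match_surfaces(toks, unique(sym_lex$surface))
      if (nrow(m) == 0) next
      ids <- vapply(m$surface, function(s) {
        if (!is.null(rec$entity_hints) && s %in% names(rec$entity_hints))
          as.character(rec$entity_hints[[s]])
        else sym_lex$entity_id[match(s, sym_lex$surface)]
      }, character(1))
      add_ent(ids, "symptom", m$surface)
      add_tri(ids, "symptom_syndrome", syn_id)
    }
    chief <- extract_chief_entities(rec$chief_complaint %||% "", chief_lex,
                                    threshold = threshold,
                                    hints = rec$entity_hints)
    if (nrow(chief)) {
      add_ent(chief$entity_id, "chief_complaint", chief$surface)
      add_tri(chief$entity_id, "chief_complaint_syndrome", syn_id)
    }
  }
  if (n_skipped > 0)
    warning(sprintf("build_kg: skipped %d record(s) with empty syndrome",
                    n_skipped))
  if (length(ent) == 0) stop("no usable records: knowledge graph is empty")
  entities <- unique(do.call(rbind, ent))
  triples <- unique(do.call(rbind, tri))
  if (add_inverse) {
    stop("inverse-edge materialization is not implemented for typed ",
         "relations; train on the stated direction")
  }
  full_surface <- stats::setNames(entities$entity_id, entities$entity_id)
  full_surface[names(surface)] <- surface
  kgraph(entities, triples, surface = full_surface)
}

#' Per-category entity counts and per-relation triple counts
#'
#' @param kg A `kgraph`.
#' @return List with `entity_counts` (named by category, stable order),
#'   `triple_counts` (named by relation, stable order), `n_entities`,
#'   `n_triples`.
#' @export
kg_stats <- function(kg) {
  ec <- vapply(KG_CATEGORIES, function(cat)
    sum(kg$entities$category == cat), integer(1))
  tc <- vapply(KG_RELATIONS, function(rel)
    sum(kg$triples$relation == rel), integer(1))
  list(entity_counts = ec, triple_counts = tc,
       n_entities = nrow(kg$entities), n_triples = nrow(kg$triples))
}

#' @export
print.kgraph <- function(x, ...) {
  s <- kg_stats(x)
  cat("Knowledge graph:", s$n_entities, "entities,", s$n_triples,
      "triples\n")
  for (rel in names(s$triple_counts))
    cat(sprintf("  %-26s %d\n", rel, s$triple_counts[[rel]]))
  invisible(x)
}

#' Write / read a knowledge graph as tab-separated files
#'
#' `triples.tsv` holds columns `head`, `relation`, `tail` (with header);
#' `entities.tsv` holds `entity_id`, `category`, `surface`. The round trip
#' `read_kgraph(write_kgraph(kg, dir))` reproduces an equal graph.
#'
#' @param kg A `kgraph`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_kgraph <- function(kg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(kg$triples, file.path(dir, "triples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ent <- kg$entities
  ent$surface <- unname(kg_surfaces(kg)[ent$entity_id])
  utils::write.table(ent, file.path(dir, "entities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_kgraph
#' @export
read_kgraph <- function(dir) {
  triples <- utils::read.delim(file.path(dir, "triples.tsv"),
                               colClasses = "character")
  ent <- utils::read.delim(file.path(dir, "entities.tsv"),
                           colClasses = "character")
  surface <- stats::setNames(ent$surface %||% ent$entity_id, ent$entity_id)
  kgraph(ent[, c("entity_id", "category")], triples, surface = surface)
}
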