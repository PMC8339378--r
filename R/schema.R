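# Concept schema (T-Box), relation inventory and constraint set (R-Box).
#
# Concepts form a rooted DAG (multi-parent edges only where the domain model
# requires them, e.g. the dual task/behavior representation of learning).
# Relations all have Person as domain and either a concept or a literal kind
# (date/text/coordinate) as range. Constraints carry functionality flags,
# ordered qualitative-level vocabularies and disjointness.

#' Create an empty concept schema
#'
#' @return an object of class `cco_schema` with no concepts or relations.
#' @seealso [core_schema()] for the shipped psychological schema.
#' @export
ontology_schema <- function() {
  structure(
    list(
      concepts = list(),
      relations = list(),
      constraints = list(
        functional = character(0),
        level_vocab = list(),
        disjoint = list()
      )
    ),
    class = "cco_schema"
  )
}

#' Add a concept to a schema
#'
#' @param schema a `cco_schema`.
#' @param label human-readable concept label (unique after case/whitespace
#'   normalization).
#' @param parents character vector of parent concept labels or ids; must
#'   already exist in the schema. Empty for root concepts.
#' @param source provenance tag, one of `core`, `emotions-onto`, `emoca`,
#'   `helis`, `paper-extension`.
#' @param factor optional factor tag in `general`, `character`, `behavior`,
#'   `situation`, `learning`.
#' @param id optional explicit id; defaults to `cco_id(label)`.
#' @return the updated schema.
#' @export
add_concept <- function(schema, label, parents = character(0),
                        source = "core", factor = NULL, id = NULL) {
  stopifnot(inherits(schema, "cco_schema"))
  id <- id %||% cco_id(label)
  if (id %in% names(schema$concepts)) {
    stop_psychonto(sprintf("duplicate concept id '%s'", id),
                   "psychonto_schema_integrity_error")
  }
  labels_norm <- vapply(schema$concepts, function(co) norm_name(co$label), "")
  if (norm_name(label) %in% labels_norm) {
    stop_psychonto(sprintf("duplicate concept label '%s'", label),
                   "psychonto_schema_integrity_error")
  }
  source <- match.arg(source,
    c("core", "emotions-onto", "emoca", "helis", "paper-extension"))
  if (!is.null(factor)) {
    factor <- match.arg(factor,
      c("general", "character", "behavior", "situation", "learning"),
      several.ok = TRUE)
  }
  parent_ids <- vapply(parents, function(p) resolve_concept(schema, p), "")
  schema$concepts[[id]] <- list(
    id = id, label = label, parents = unname(parent_ids),
    source = source, factor = factor
  )
  if (has_cycle(schema)) {
    stop_psychonto(sprintf("adding '%s' creates a cycle", label),
                   "psychonto_schema_integrity_error")
  }
  schema
}

#' Add a relation definition to a schema
#'
#' Relations are person-to-concept (or person-to-literal) properties. The
#' same name may be declared twice with distinct ranges (the dual `hasAffect`
#' representation: a discrete affective-process object and a valence/arousal
#' coordinate object).
#'
#' @param schema a `cco_schema`.
#' @param name relation name, e.g. `"hasSleepHygiene"`.
#' @param range concept label/id, or a literal kind when
#'   `range_kind != "concept"`.
#' @param factor factor group the relation maps to (`general`, `character`,
#'   `behavior`, `situation`, `learning`).
#' @param functional if `TRUE`, at most one input value per person per wave.
#' @param parent optional super-property name (e.g. trait relations are
#'   sub-properties of `hasPersonality`).
#' @param source provenance tag.
#' @param range_kind `"concept"`, `"date"`, `"text"` or `"coordinate"`.
#' @return the updated schema.
#' @export
add_relation <- function(schema, name, range, factor,
                         functional = FALSE, parent = NULL,
                         source = "core", range_kind = "concept") {
  stopifnot(inherits(schema, "cco_schema"))
  range_kind <- match.arg(range_kind, c("concept", "date", "text", "coordinate"))
  factor <- match.arg(factor,
    c("general", "character", "behavior", "situation", "learning"))
  range_id <- if (range_kind == "concept") {
    resolve_concept(schema, range)
  } else if (range_kind == "coordinate") {
    tryCatch(resolve_concept(schema, range), error = function(e) "cco:coordinate")
  } else {
    range
  }
  key <- paste(name, range_id, sep = "|")
  if (key %in% names(schema$relations)) {
    stop_psychonto(sprintf("duplicate relation '%s' with range '%s'", name, range_id),
                   "psychonto_schema_integrity_error")
  }
  if (!is.null(parent) && !parent %in% relation_names(schema)) {
    stop_psychonto(sprintf("unknown parent relation '%s'", parent),
                   "psychonto_lookup_error")
  }
  schema$relations[[key]] <- list(
    name = name, domain = "cco:person", range = range_id,
    range_kind = range_kind, factor = factor, functional = functional,
    parent = parent, source = source
  )
  if (functional &&
      !name %in% schema$constraints$functional) {
    schema$constraints$functional <- c(schema$constraints$functional, name)
  }
  schema
}

# Register an ordered qualitative-level vocabulary for a concept: creates
# "<Level> <Label>" subclasses and records the ordering (used for adjacency-
# tolerant disjointness in consistency checking).
add_level_vocab <- function(schema, concept,
                            levels = c("Low", "Medium", "High"),
                            source = "core") {
  cid <- resolve_concept(schema, concept)
  base <- schema$concepts[[cid]]$label
  ids <- character(0)
  for (lv in levels) {
    lab <- paste(lv, base)
    schema <- add_concept(schema, lab, parents = cid, source = source)
    ids <- c(ids, cco_id(lab))
  }
  schema$constraints$level_vocab[[cid]] <- ids
  schema
}

#' Declare a disjoint concept pair
#'
#' @param schema a `cco_schema`.
#' @param a,b concept labels or ids.
#' @return the updated schema.
#' @export
add_disjoint <- function(schema, a, b) {
  pa <- resolve_concept(schema, a)
  pb <- resolve_concept(schema, b)
  schema$constraints$disjoint <-
    c(schema$constraints$disjoint, list(sort(c(pa, pb))))
  schema
}

# -- lookup ------------------------------------------------------------------

#' Resolve a concept label or id to its id
#'
#' @param schema a `cco_schema`.
#' @param x concept id (`cco:...`) or label (matched after normalization).
#' @return the concept id.
#' @export
resolve_concept <- function(schema, x) {
  stopifnot(length(x) == 1L, is.character(x))
  if (x %in% names(schema$concepts)) return(x)
  guess <- cco_id(x)
  if (guess %in% names(schema$concepts)) return(guess)
  labels_norm <- vapply(schema$concepts, function(co) norm_name(co$label), "")
  hit <- names(schema$concepts)[labels_norm == norm_name(x)]
  if (length(hit) == 1L) return(hit)
  stop_psychonto(sprintf("unknown concept '%s'", x), "psychonto_lookup_error")
}

relation_names <- function(schema) {
  unique(vapply(schema$relations, `[[`, "", "name"))
}

#' Look up relation definitions by name
#'
#' @param schema a `cco_schema`.
#' @param name relation name (normalization-tolerant, so the irregular
#'   spacing of hand-written rules, e.g. `"has Sleep Hygiene"`, resolves).
#' @return list of relation definitions (length 2 for the dual `hasAffect`).
#' @export
get_relations <- function(schema, name) {
  nms <- vapply(schema$relations, `[[`, "", "name")
  defs <- schema$relations[norm_name(nms) == norm_name(name)]
  if (length(defs) == 0L) {
    stop_psychonto(sprintf("unknown relation '%s'", name), "psychonto_lookup_error")
  }
  unname(defs)
}

# all super-property names of a relation name, inclusive
relation_ancestors <- function(schema, name) {
  out <- name
  cur <- name
  repeat {
    defs <- get_relations(schema, cur)
    par <- defs[[1]]$parent
    if (is.null(par)) break
    out <- c(out, par)
    cur <- par
  }
  out
}

# -- graph queries -----------------------------------------------------------

has_cycle <- function(schema) {
  # Kahn topological sort over parent edges
  ids <- names(schema$concepts)
  indeg <- vapply(schema$concepts, function(co) length(co$parents), 0L)
  children <- lapply(ids, function(i) character(0))
  names(children) <- ids
  for (co in schema$concepts) {
    for (p in co$parents) children[[p]] <- c(children[[p]], co$id)
  }
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen < length(ids)
}

#' All ancestors of a concept (reflexive)
#'
#' @param schema a `cco_schema`.
#' @param x concept label or id.
#' @return character vector of ancestor ids, including `x` itself.
#' @export
concept_ancestors <- function(schema, x) {
  id <- resolve_concept(schema, x)
  out <- character(0)
  queue <- id
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (v %in% out) next
    out <- c(out, v)
    queue <- c(queue, schema$concepts[[v]]$parents)
  }
  out
}

#' Subsumption test
#'
#' `TRUE` iff `ancestor` is reachable from `child` via parent edges
#' (reflexive, so every concept subsumes itself).
#'
#' @param schema a `cco_schema`.
#' @param child,ancestor concept labels or ids.
#' @return logical flag.
#' @examples
#' s <- core_schema()
#' is_subclass_of(s, "Pain", "Bodily Feeling")
#' @export
is_subclass_of <- function(schema, child, ancestor) {
  aid <- resolve_concept(schema, ancestor)
  aid %in% concept_ancestors(schema, child)
}

#' All descendants of a concept (reflexive)
#'
#' @inheritParams concept_ancestors
#' @return character vector of descendant ids.
#' @export
concept_descendants <- function(schema, x) {
  id <- resolve_concept(schema, x)
  ids <- names(schema$concepts)
  ids[vapply(ids, function(c) id %in% concept_ancestors(schema, c), NA)]
}

#' Direct subclasses of a concept
#'
#' @inheritParams concept_ancestors
#' @return character vector of child ids.
#' @export
direct_subclasses <- function(schema, x) {
  id <- resolve_concept(schema, x)
  ids <- names(schema$concepts)
  ids[vapply(schema$concepts, function(co) id %in% co$parents, NA)]
}

#' Factor group(s) a concept belongs to
#'
#' Walks the ancestor closure and collects every factor tag found; concepts
#' with dual parentage (the learning task/behavior representation) belong to
#' several factor groups at once.
#'
#' @param schema a `cco_schema`.
#' @param x concept label or id.
#' @return character vector of factor tags (sorted, unique).
#' @examples
#' s <- core_schema()
#' top_category(s, "Sleep Hygiene")   # "behavior"
#' @export
top_category <- function(schema, x) {
  anc <- concept_ancestors(schema, x)
  tags <- unlist(lapply(anc, function(a) schema$concepts[[a]]$factor))
  if (is.null(tags) || length(tags) == 0L) {
    stop_psychonto(
      sprintf("concept '%s' has no factor-tagged ancestor", x),
      "psychonto_classification_error")
  }
  sort(unique(tags))
}

#' Validate schema integrity
#'
#' Checks acyclicity, parent existence, label uniqueness and that every
#' concept-ranged relation resolves. Called by [core_schema()] and available
#' after any extension.
#'
#' @param schema a `cco_schema`.
#' @return invisibly `TRUE`; errors on violation.
#' @export
validate_schema <- function(schema) {
  if (has_cycle(schema)) {
    stop_psychonto("concept graph has a cycle", "psychonto_schema_integrity_error")
  }
  for (co in schema$concepts) {
    bad <- setdiff(co$parents, names(schema$concepts))
    if (length(bad)) {
      stop_psychonto(sprintf("concept '%s' has unknown parent '%s'",
                             co$id, bad[[1]]),
                     "psychonto_schema_integrity_error")
    }
  }
  labs <- vapply(schema$concepts, function(co) norm_name(co$label), "")
  if (anyDuplicated(labs)) {
    stop_psychonto("duplicate normalized labels", "psychonto_schema_integrity_error")
  }
  for (r in schema$relations) {
    if (r$range_kind == "concept" && !r$range %in% names(schema$concepts)) {
      stop_psychonto(sprintf("relation '%s' range '%s' missing", r$name, r$range),
                     "psychonto_schema_integrity_error")
    }
  }
  for (p in schema$constraints$disjoint) {
    if (!all(p %in% names(schema$concepts))) {
      stop_psychonto("disjointness constraint references unknown concept",
                     "psychonto_schema_integrity_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.cco_schema <- function(x, ...) {
  cat(sprintf("<cco_schema> %d concepts, %d relation definitions, %d level vocabularies\n",
              length(x$concepts), length(x$relations),
              length(x$constraints$level_vocab)))
  invisible(x)
}
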